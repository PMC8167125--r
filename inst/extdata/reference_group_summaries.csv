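table,variable,group,mean,sd,n
manual,latency_end_intensity_gu,benign,16.4,22.14,5
manual,latency_end_intensity_gu,cancer,11.33,10.97,3
manual,latency_end_intensity_gu,control,17.25,18.39,8
manual,latency_end_time_s,benign,15.87,11.59,5
manual,latency_end_time_s,cancer,12.1,5.58,3
manual,latency_end_time_s,control,21.23,18.93,8
manual,f_max_gu,benign,165.8,11.69,5
manual,f_max_gu,cancer,202,35.68,3
manual,f_max_gu,control,169.63,12.84,8
manual,rise_gu,benign,149.4,23.46,5
manual,rise_gu,cancer,190.67,41.43,3
manual,rise_gu,control,152.38,29.31,8
manual,t_max_s,benign,60.95,23.56,5
manual,t_max_s,cancer,351.82,307.08,3
manual,t_max_s,control,84,43.88,8
manual,time_to_rise_s,benign,45.08,30.56,5
manual,time_to_rise_s,cancer,339.73,312.21,3
manual,time_to_rise_s,control,62.77,53.8,8
manual,upslope_gradient_gu_per_s,benign,5.5,4.34,5
manual,upslope_gradient_gu_per_s,cancer,1.51,1.89,3
manual,upslope_gradient_gu_per_s,control,4.7,4.43,8
manual,f_half_gu,benign,74.7,11.73,5
manual,f_half_gu,cancer,95.33,20.71,3
manual,f_half_gu,control,76.19,14.65,8
manual,t_half_s,benign,12.77,12.77,5
manual,t_half_s,cancer,69.92,67.88,3
manual,t_half_s,control,14.01,11.7,8
manual,t_half_over_t_max,benign,0.2,0.18,5
manual,t_half_over_t_max,cancer,0.31,0.32,3
manual,t_half_over_t_max,control,0.2,0.21,8
manual,t100_s,benign,160.95,23.56,5
manual,t100_s,cancer,451.82,307.08,3
manual,t100_s,control,184,43.88,8
manual,f100_gu,benign,133,11.85,5
manual,f100_gu,cancer,143.33,39.8,3
manual,f100_gu,control,121.13,28.39,8
manual,fall100_gu,benign,32.8,7.73,5
manual,fall100_gu,cancer,58.67,74.23,3
manual,fall100_gu,control,48.5,20.17,8
manual,downslope100_gu_per_s,benign,0.33,0.08,5
manual,downslope100_gu_per_s,cancer,0.59,0.74,3
manual,downslope100_gu_per_s,control,0.49,0.2,8
manual,tracking_length_s,benign,1767.6,154.21,5
manual,tracking_length_s,cancer,2134.67,153.44,3
manual,tracking_length_s,control,1902.63,240.72,8
manual,time_after_tmax_s,benign,1706.65,166.86,5
manual,time_after_tmax_s,cancer,1782.84,460.45,3
manual,time_after_tmax_s,control,1818.62,235.59,8
manual,final_intensity_gu,benign,46,29.56,5
manual,final_intensity_gu,cancer,64.33,16.86,3
manual,final_intensity_gu,control,38,26.94,8
manual,downslope_gradient_gu_per_s,benign,0.07,0.03,5
manual,downslope_gradient_gu_per_s,cancer,0.08,0.02,3
manual,downslope_gradient_gu_per_s,control,0.07,0.02,8
manual,kurtosis,benign,0.73,3.32,5
manual,kurtosis,cancer,0.62,1.57,3
manual,kurtosis,control,-0.17,1.23,8
manual,skew,benign,-0.29,0.87,5
manual,skew,cancer,0.17,0.18,3
manual,skew,control,0.19,0.46,8
tracker,latency_end_intensity_gu,benign,14.62,15.14,11
tracker,latency_end_intensity_gu,cancer,15.91,10.23,9
tracker,latency_end_intensity_gu,control,19.95,17.24,20
tracker,latency_end_time_s,benign,11.54,14.35,11
tracker,latency_end_time_s,cancer,26.43,29.59,9
tracker,latency_end_time_s,control,17.91,19.85,20
tracker,f_max_gu,benign,153.22,23.37,11
tracker,f_max_gu,cancer,136.43,22.61,9
tracker,f_max_gu,control,144.82,29.37,20
tracker,rise_gu,benign,138.59,27.89,11
tracker,rise_gu,cancer,120.52,25.93,9
tracker,rise_gu,control,124.87,31.45,20
tracker,t_max_s,benign,83.56,89.18,11
tracker,t_max_s,cancer,190.18,138.81,9
tracker,t_max_s,control,72.62,65.88,20
tracker,time_to_rise_s,benign,72.02,92.3,11
tracker,time_to_rise_s,cancer,163.75,129.01,9
tracker,time_to_rise_s,control,54.71,60.51,20
tracker,upslope_gradient_gu_per_s,benign,4.18,3.39,11
tracker,upslope_gradient_gu_per_s,cancer,1.73,1.66,9
tracker,upslope_gradient_gu_per_s,control,4.44,3.48,20
tracker,f_half_gu,benign,69.3,13.95,11
tracker,f_half_gu,cancer,60.26,12.96,9
tracker,f_half_gu,control,62.43,15.72,20
tracker,t_half_s,benign,11.8,6.74,11
tracker,t_half_s,cancer,11.24,6.28,9
tracker,t_half_s,control,13.19,11.8,20
tracker,t_half_over_t_max,benign,0.21,0.11,11
tracker,t_half_over_t_max,cancer,0.15,0.15,9
tracker,t_half_over_t_max,control,0.24,0.13,20
tracker,t100_s,benign,183.56,89.18,11
tracker,t100_s,cancer,290.18,138.81,9
tracker,t100_s,control,172.62,65.88,20
tracker,f100_gu,benign,109.36,30.77,11
tracker,f100_gu,cancer,111.37,19.9,9
tracker,f100_gu,control,106.98,34.68,20
tracker,fall100_gu,benign,43.86,18.67,11
tracker,fall100_gu,cancer,25.07,16.15,9
tracker,fall100_gu,control,37.84,18.52,20
tracker,downslope100_gu_per_s,benign,0.44,0.19,11
tracker,downslope100_gu_per_s,cancer,0.25,0.16,9
tracker,downslope100_gu_per_s,control,0.38,0.19,20
tracker,tracking_length_s,benign,612.19,354.53,11
tracker,tracking_length_s,cancer,595,320.69,9
tracker,tracking_length_s,control,598.09,334.76,20
tracker,time_after_tmax_s,benign,528.63,339.73,11
tracker,time_after_tmax_s,cancer,404.82,372.37,9
tracker,time_after_tmax_s,control,525.47,368.56,20
tracker,final_intensity_gu,benign,82.75,48.13,11
tracker,final_intensity_gu,cancer,94,31.18,9
tracker,final_intensity_gu,control,78.15,43.13,20
tracker,downslope_gradient_gu_per_s,benign,0.16,0.1,11
tracker,downslope_gradient_gu_per_s,cancer,0.2,0.22,9
tracker,downslope_gradient_gu_per_s,control,0.21,0.26,20
tracker,kurtosis,benign,5.12,6.77,11
tracker,kurtosis,cancer,6.51,7.92,9
tracker,kurtosis,control,2.68,4.17,20
tracker,skew,benign,-0.89,1.72,11
tracker,skew,cancer,-1.69,1.17,9
tracker,skew,control,-0.41,1.37,20
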