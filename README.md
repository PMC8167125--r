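# fluotrack

Dynamic quantification of indocyanine green (ICG) fluorescence angiograms
from dual-channel (white-light + near-infrared) endoscopy.

## The problem

Intravenous ICG reaches colorectal tissue within seconds and fluoresces
under near-infrared (NIR) illumination. Malignant tissue takes the dye up
late and retains it — a consequence of chaotic neovasculature and absent
lymphatic clearance — while normal mucosa and most benign lesions wash in
and clear briskly. Those differences live in the *shape* of the
time–intensity curve, not in any single snapshot, so quantifying them
requires following a surgeon-annotated region of interest (ROI) through a
moving endoscopic video and logging the mean NIR grey value (0–255 "grey
units", g.u.) under it, frame by frame.

`fluotrack` is for imaging scientists and surgical researchers who have
such dual-channel recordings (or want to prototype against synthetic
ones). It provides:

* **Video I/O** — synchronized frame-pair streams from side-by-side or
  two-source PNG/TIFF sequences, JSON ROI annotations, CSV intensity
  traces (`load_stream()`, `read_annotations()`, `read_trace()`).
* **ROI tracking** — minimum-eigenvalue (Shi–Tomasi) feature detection
  inside each ROI, pyramidal Kanade–Lucas–Tomasi optical flow with a
  forward–backward consistency check, robust similarity propagation of
  the polygon, gap logging and re-initialization (`run_tracking()`).
* **Intensity extraction** — per-frame polygon means in the NIR channel,
  25×25 spot means on stills, photobleaching assessment
  (`extract_trace()`, `spot_mean()`, `photobleach_assess()`).
* **Kinetic milestones** — for each trace: baseline; latency end (first
  smoothed rise of 5 g.u. above baseline); peak F_max and its time T_max;
  rise = F_max − latency intensity and the upslope gradient
  rise / time-to-rise; half-rise F_½max = rise/2 and T_½max; the washout
  flag 100 s after the peak (T_100 = T_max + 100, F_100,
  Fall_100 = F_max − F_100, DownSlope_100 = Fall_100/100); tracking
  length, final intensity, downslope gradient, skew and excess kurtosis
  (`compute_profile()`, `fit_log_curve()`, `group_mean_curves()`).
* **Group statistics** — mean ± SD tables per tissue group with
  Kruskal–Wallis and pairwise Mann–Whitney U tests, Wilcoxon signed-rank
  for paired groupings (`build_group_table()`, `mann_whitney_u()`, ...).
* **KNN grouping** — per-point dynamic signatures (latency-aligned
  resampled intensities + milestone summaries, z-scored) assigned to
  tumour/control clusters by a seeded K-nearest-neighbour rule
  (`build_signatures()`, `knn_group()`, `compare_groupings()`).
* **Synthetic generator** — gamma-variate inflow + retention kinetics
  with analytic milestone truth, labelled cohorts, and fully
  ground-truthed dual-channel videos with camera motion and occlusions
  (`curve_params()`, `simulate_trace()`, `simulate_cohort()`,
  `simulate_video()`).

Everything is tibble-first and pipe-friendly; fitted objects support
`tidy()`/`glance()`, result types have `autoplot()`/`plot_*()` methods,
and a thin CLI (`inst/cli/fluotrack.R`) exposes the pipeline to shell
users (`track`, `kinetics`, `stats`, `photobleach`, `spot`, `simulate`).

## Worked example

Simulate a labelled cohort (5 subjects per tissue group, 10 minutes at
30 fps), reduce every trace to its milestone profile, and compare groups:

```r
library(fluotrack)
library(dplyr)

cohort <- simulate_cohort(n_per_group = 5, fps = 30, duration_s = 600, seed = 7)
profiles <- bind_rows(lapply(cohort$traces, compute_profile))
profiles |>
  select(roi_label, tissue_class, t_max_s, rise_gu,
         upslope_gradient_gu_per_s, fall100_gu) |>
  head(3)
#> # A tibble: 3 × 6
#>   roi_label tissue_class t_max_s rise_gu upslope_gradient_gu_per_s fall100_gu
#>   <chr>     <chr>          <dbl>   <dbl>                     <dbl>      <dbl>
#> 1 benign_01 benign          66.0    232.                      4.35      176.
#> 2 benign_02 benign          68.1    106.                      1.97       75.5
#> 3 benign_03 benign         133.     145.                      1.25       43.8

tab <- build_group_table(profiles)
tab |>
  filter(variable %in% c("t_max_s", "upslope_gradient_gu_per_s", "fall100_gu")) |>
  select(variable, mean_benign, mean_cancer, mean_control,
         kruskal_wallis_p, p_cancer_vs_control)
#> # A tibble: 3 × 6
#>   variable                 mean_benign mean_cancer mean_control kruskal_wallis_p p_cancer_vs_control
#>   <chr>                          <dbl>       <dbl>        <dbl>            <dbl>               <dbl>
#> 1 t_max_s                        88.1      185.           81.1           0.00865             0.00794
#> 2 upslope_gradient_gu_per…        2.43       0.836         2.03          0.00900             0.00794
#> 3 fall100_gu                     97.1       21.8          81.1           0.00900             0.00794
```

Read: simulated cancers peak at ~185 s versus ~81 s for normal tissue,
rise with roughly a third of the gradient, and shed only ~22 g.u. in the
100 s after the peak versus ~81–97 g.u. for benign/control — the
dye-retention phenotype — and even at n = 5 per group the Mann–Whitney
contrast between cancer and control is p ≈ 0.008 for all three
variables.

For video work, `simulate_video()` returns a frame stream plus complete
ground truth (per-frame polygons, true region intensities), and
`run_tracking() |> extract_trace() |> compute_profile()` closes the loop;
see the vignette (`vignettes/fluorescence-kinetics.Rmd`) for the model
and every definitional choice.

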