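#' Kinetic milestone analysis of fluorescence inflow/washout curves
#'
#' After intravenous indocyanine green, the ROI-mean NIR intensity follows
#' a characteristic course: a latency period at baseline, a rapid inflow to
#' a peak, and a slow washout. [compute_profile()] reduces one trace to the
#' standard milestone variables used for tissue comparison:
#'
#' * latency end: first sample whose smoothed intensity rises 5 grey units
#'   above baseline (baseline = mean of the first seconds of the trace);
#' * `f_max_gu` / `t_max_s`: peak smoothed intensity and its time;
#' * `rise_gu` = f_max - latency-end intensity; `time_to_rise_s` = t_max -
#'   latency-end time; `upslope_gradient_gu_per_s` = rise / time-to-rise;
#' * `f_half_gu` = rise / 2 and `t_half_s`, the time from latency end until
#'   the smoothed curve first reaches latency-end intensity + rise / 2;
#' * the washout flag 100 s after the peak: `t100_s` = t_max + 100,
#'   `f100_gu` (smoothed intensity there, linearly interpolated),
#'   `fall100_gu` = f_max - f100, `downslope100_gu_per_s` = fall100 / 100;
#' * whole-curve descriptors: tracking length, time after the peak, final
#'   intensity, overall downslope gradient, sample skew and excess
#'   kurtosis of the raw intensities.
#'
#' All times are on the trace's own clock (first analyzed frame = 0 s).
#'
#' @name kinetics
NULL

# Centered moving average with shrinking windows at the edges.
moving_average <- function(v, w) {
  n <- length(v)
  if (w <= 1 || n == 0) return(v)
  h <- w %/% 2
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Raw sample moments: skewness g1 = m3 / m2^(3/2) and excess kurtosis
# g2 = m4 / m2^2 - 3 (normal = 0), population-moment convention.
sample_skewness <- function(v) {
  m <- mean(v); m2 <- mean((v - m)^2)
  if (m2 == 0) return(0)
  mean((v - m)^3) / m2^1.5
}

sample_excess_kurtosis <- function(v) {
  m <- mean(v); m2 <- mean((v - m)^2)
  if (m2 == 0) return(0)
  mean((v - m)^4) / m2^2 - 3
}

trace_samples <- function(trace) {
  ok <- !trace$gap_flag & !is.na(trace$intensity_gu)
  list(t = trace$time_s[ok], v = trace$intensity_gu[ok])
}

smoothing_width <- function(smoothing_window_s, fps) {
  w <- max(1L, as.integer(round(smoothing_window_s * fps)))
  if (w %% 2 == 0) w <- w + 1L
  w
}

#' Detect the end of the latency period
#'
#' The latency period ends at the first sample whose smoothed intensity
#' reaches `baseline + rise_threshold_gu`, where the baseline is the mean
#' smoothed intensity over the first `baseline_window_s` seconds of the
#' trace (annotation precedes fluorescence onset, so early frames are
#' pre-inflow).
#'
#' @param trace An intensity trace.
#' @param rise_threshold_gu Rise above baseline marking the inflow start
#'   (5 grey units by convention).
#' @param baseline_window_s Baseline estimation window (default 3 s).
#' @param smoothing_window_s Centered moving-average window applied before
#'   detection (seconds; values below one sampling interval leave the
#'   curve raw).
#' @return List with `time_s`, `intensity_gu` (smoothed value at the
#'   crossing sample), `baseline_gu` and the sample `index`.
#' @export
detect_latency_end <- function(trace, rise_threshold_gu = 5,
                               baseline_window_s = 3, smoothing_window_s = 1) {
  s <- trace_samples(trace)
  if (length(s$t) == 0) abort("empty trace", class = "fluotrack_validation_error")
  fps <- trace_meta(trace)$fps_effective
  sm <- moving_average(s$v, smoothing_width(smoothing_window_s, fps))
  base_idx <- s$t <= s$t[1] + baseline_window_s
  baseline <- mean(sm[base_idx])
  idx <- which(sm >= baseline + rise_threshold_gu)
  if (length(idx) == 0) {
    abort(sprintf("no inflow detected: intensity never rises %g g.u. above baseline (%.2f)",
                  rise_threshold_gu, baseline),
          class = "fluotrack_no_inflow")
  }
  i <- idx[1]
  list(time_s = s$t[i], intensity_gu = sm[i], baseline_gu = baseline, index = i)
}

#' The kinetic variables reported per trace
#'
#' Fixed, ordered list of the milestone variables a [compute_profile()]
#' row exposes for group comparison.
#'
#' @return Character vector of column names.
#' @export
kinetic_variables <- function() {
  c("latency_end_intensity_gu", "latency_end_time_s", "f_max_gu", "rise_gu",
    "t_max_s", "time_to_rise_s", "upslope_gradient_gu_per_s",
    "f_half_gu", "t_half_s", "t_half_over_t_max",
    "t100_s", "f100_gu", "fall100_gu", "downslope100_gu_per_s",
    "tracking_length_s", "time_after_tmax_s", "final_intensity_gu",
    "downslope_gradient_gu_per_s", "kurtosis", "skew")
}

#' Compute the kinetic milestone profile of a trace
#'
#' See [kinetics] for the variable definitions. The peak is located on the
#' smoothed curve (raw high-rate maxima are noise-dominated; set
#' `smoothing_window_s = 0` for the raw regime). Traces ending before
#' `t_max + 100` s yield a partial profile with the post-peak washout
#' fields `NA` and `complete = FALSE`. Skew and kurtosis are computed on
#' the raw non-gap samples.
#'
#' @inheritParams detect_latency_end
#' @param upslope_mode `"rise_over_time_to_rise"` (gradient from the end of
#'   latency to the peak; default) or `"fmax_over_tmax"` (the cruder
#'   peak-over-time ratio, offered for comparability).
#' @return A one-row `kinetic_profile` tibble: `roi_label`,
#'   `tissue_class`, `baseline_gu`, every [kinetic_variables()] column,
#'   and `complete`.
#' @export
compute_profile <- function(trace, smoothing_window_s = 1.0,
                            rise_threshold_gu = 5, baseline_window_s = 3,
                            upslope_mode = c("rise_over_time_to_rise",
                                             "fmax_over_tmax")) {
  upslope_mode <- match.arg(upslope_mode)
  meta <- trace_meta(trace)
  s <- trace_samples(trace)
  n <- length(s$t)
  fps <- meta$fps_effective
  w <- smoothing_width(smoothing_window_s, fps)
  if (n < max(w, 3)) {
    abort("trace shorter than the smoothing window",
          class = "fluotrack_validation_error")
  }
  sm <- moving_average(s$v, w)
  lat <- detect_latency_end(trace, rise_threshold_gu, baseline_window_s,
                            smoothing_window_s)
  i_max <- which.max(sm)
  if (i_max == n) {
    abort("trace ends at its maximum: no post-peak samples",
          class = "fluotrack_validation_error")
  }
  f_max <- sm[i_max]
  t_max <- s$t[i_max]
  rise <- f_max - lat$intensity_gu
  time_to_rise <- t_max - lat$time_s
  upslope <- if (upslope_mode == "rise_over_time_to_rise") {
    if (time_to_rise > 0) rise / time_to_rise else NA_real_
  } else {
    if (t_max > 0) f_max / t_max else NA_real_
  }
  f_half <- rise / 2
  half_level <- lat$intensity_gu + f_half
  t_half <- NA_real_
  post <- seq(lat$index, i_max)
  cross <- post[which(sm[post] >= half_level)]
  if (length(cross) > 0) {
    i <- cross[1]
    if (i > 1 && sm[i - 1] < half_level && sm[i] > sm[i - 1]) {
      frac <- (half_level - sm[i - 1]) / (sm[i] - sm[i - 1])
      t_half <- s$t[i - 1] + frac * (s$t[i] - s$t[i - 1]) - lat$time_s
    } else {
      t_half <- s$t[i] - lat$time_s
    }
  }
  t100 <- t_max + 100
  t_last <- s$t[n]
  complete <- t_last >= t100
  if (complete) {
    f100 <- approx(s$t, sm, xout = t100)$y
    fall100 <- f_max - f100
    downslope100 <- fall100 / 100
  } else {
    f100 <- fall100 <- downslope100 <- NA_real_
  }
  tracking_length <- t_last
  time_after_tmax <- tracking_length - t_max
  final_intensity <- sm[n]
  downslope_gradient <- if (time_after_tmax > 0) {
    (f_max - final_intensity) / time_after_tmax
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    roi_label = meta$roi_label, tissue_class = meta$tissue_class,
    baseline_gu = lat$baseline_gu,
    latency_end_intensity_gu = lat$intensity_gu,
    latency_end_time_s = lat$time_s,
    f_max_gu = f_max, rise_gu = rise, t_max_s = t_max,
    time_to_rise_s = time_to_rise,
    upslope_gradient_gu_per_s = upslope,
    f_half_gu = f_half, t_half_s = t_half,
    t_half_over_t_max = if (!is.na(t_half) && t_max > 0) t_half / t_max else NA_real_,
    t100_s = t100, f100_gu = f100, fall100_gu = fall100,
    downslope100_gu_per_s = downslope100,
    tracking_length_s = tracking_length,
    time_after_tmax_s = time_after_tmax,
    final_intensity_gu = final_intensity,
    downslope_gradient_gu_per_s = downslope_gradient,
    kurtosis = sample_excess_kurtosis(s$v),
    skew = sample_skewness(s$v),
    complete = complete)
  class(out) <- c("kinetic_profile", class(out))
  out
}

#' Fit a logarithmic trend to the post-latency signal
#'
#' Least-squares fit of `intensity = a * ln(t - t_latency_end + 1) + b`
#' over all non-gap samples at or after the latency end, summarizing the
#' saturating shape of group mean curves.
#'
#' @param trace An intensity trace.
#' @param t_latency_end_s Known inflow-start time; detected from the trace
#'   when `NULL`.
#' @inheritParams detect_latency_end
#' @return A `log_fit` object with `a`, `b`, `r_squared`, `n`,
#'   `t_latency_end_s`; supports [tidy()] and [glance()]. A zero-variance
#'   response yields `a = 0`, `b = ` the constant, `r_squared = 0` by
#'   convention.
#' @export
fit_log_curve <- function(trace, rise_threshold_gu = 5, baseline_window_s = 3,
                          smoothing_window_s = 1, t_latency_end_s = NULL) {
  s <- trace_samples(trace)
  lat_time <- t_latency_end_s %||%
    detect_latency_end(trace, rise_threshold_gu, baseline_window_s,
                       smoothing_window_s)$time_s
  keep <- s$t >= lat_time
  t <- s$t[keep]; y <- s$v[keep]
  if (length(t) < 3) {
    abort("fewer than 3 usable samples after latency end",
          class = "fluotrack_validation_error")
  }
  x <- log(t - lat_time + 1)
  if (var(y) == 0) {
    fit <- list(a = 0, b = y[1], r_squared = 0)
  } else {
    m <- lm(y ~ x)
    ss_res <- sum(m$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    fit <- list(a = unname(coef(m)[2]), b = unname(coef(m)[1]),
                r_squared = 1 - ss_res / ss_tot)
  }
  structure(list(a = fit$a, b = fit$b, r_squared = fit$r_squared,
                 n = length(t), t_latency_end_s = lat_time),
            class = "log_fit")
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("<log_fit> intensity = %.4g * ln(t - %.2f + 1) + %.4g  (r^2 = %.4f, n = %d)\n",
              x$a, x$t_latency_end_s, x$b, x$r_squared, x$n))
  invisible(x)
}

#' @describeIn fit_log_curve Coefficients as a tidy tibble.
#' @param x A `log_fit`.
#' @param ... Unused.
#' @export
tidy.log_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @describeIn fit_log_curve One-row model summary.
#' @export
glance.log_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n,
                 t_latency_end_s = x$t_latency_end_s)
}

#' Group mean fluorescence curves
#'
#' Aligns each trace on its latency-end time (inflow start = 0), resamples
#' all traces onto a common grid by linear interpolation (gap samples
#' ignored), and averages per tissue class. The grid extends to the
#' shortest aligned coverage so every trace contributes to every grid
#' point. Classes present in `classes` but with no usable trace are
#' skipped with a warning.
#'
#' @param traces List of intensity traces (tissue class from each trace's
#'   metadata).
#' @param resample_fps Common grid rate (default 30).
#' @inheritParams detect_latency_end
#' @return Tibble: `tissue_class`, `time_s` (from latency end),
#'   `mean_intensity_gu`, `n_traces`.
#' @export
group_mean_curves <- function(traces, resample_fps = 30, rise_threshold_gu = 5,
                              baseline_window_s = 3, smoothing_window_s = 1) {
  stopifnot(length(traces) >= 1)
  aligned <- purrr::map(traces, function(tr) {
    s <- trace_samples(tr)
    lat <- detect_latency_end(tr, rise_threshold_gu, baseline_window_s,
                              smoothing_window_s)
    list(t = s$t - lat$time_s, v = s$v,
         class = trace_meta(tr)$tissue_class)
  })
  horizon <- min(purrr::map_dbl(aligned, ~ max(.x$t)))
  if (horizon <= 0) {
    abort("no common post-latency coverage across traces",
          class = "fluotrack_validation_error")
  }
  grid <- seq(0, horizon, by = 1 / resample_fps)
  classes <- unique(purrr::map_chr(aligned, "class"))
  purrr::map_dfr(classes, function(cl) {
    members <- Filter(function(a) identical(a$class, cl), aligned)
    if (length(members) == 0) {
      warn(sprintf("tissue class '%s' has no usable trace; skipped", cl))
      return(NULL)
    }
    mat <- vapply(members, function(a) approx(a$t, a$v, xout = grid)$y,
                  numeric(length(grid)))
    mat <- matrix(mat, nrow = length(grid))
    tibble::tibble(tissue_class = cl, time_s = grid,
                   mean_intensity_gu = rowMeans(mat, na.rm = TRUE),
                   n_traces = length(members))
  })
}
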