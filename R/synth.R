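#' Parametric fluorescence kinetic model
#'
#' The generator's noiseless time-intensity curve is a gamma-variate bolus
#' inflow plus a saturating retention term, with optional mono-exponential
#' photobleaching of the fluorescent signal:
#'
#' for `t < onset_s`: `baseline_gu`; for `t >= onset_s`, with
#' `s = (t - onset_s) / time_to_peak_s`:
#'
#' `baseline + A * [ (1 - rho) * s^alpha * exp(alpha * (1 - s)) +
#'  rho * (1 - exp(-(t - onset) / tau)) ] * exp(-bleach * (t - onset))`
#'
#' The gamma-variate term peaks at `s = 1` with value `A * (1 - rho)`, so
#' with `rho = 0` and no bleaching the curve peaks exactly at
#' `onset_s + time_to_peak_s` with value `baseline + A`. Raising the
#' retention fraction `rho` slows the post-peak decline — emulating the
#' dye-persistence phenotype of malignant tissue — while the gamma term
#' alone gives the brisk wash-in/wash-out of normal mucosa. Bleaching is
#' applied to the signal component only so the curve stays continuous at
#' onset for every parameter value.
#'
#' @param baseline_gu Pre-onset grey level.
#' @param onset_s Time of fluorescence arrival (s).
#' @param amplitude_gu Signal amplitude A (g.u.).
#' @param time_to_peak_s Gamma-variate peak delay after onset (s).
#' @param shape_alpha Gamma-variate shape (> 0; larger = more symmetric).
#' @param retention_fraction Fraction of the amplitude that is retained
#'   (0-1).
#' @param washout_tau_s Retention build-up time constant (s).
#' @param noise_sd_gu Additive Gaussian noise SD for sampled traces.
#' @param bleach_rate_per_s Mono-exponential bleaching rate (>= 0).
#' @return A validated `curve_params` list.
#' @export
curve_params <- function(baseline_gu = 10, onset_s = 10, amplitude_gu = 140,
                         time_to_peak_s = 60, shape_alpha = 2,
                         retention_fraction = 0.1, washout_tau_s = 60,
                         noise_sd_gu = 0, bleach_rate_per_s = 0) {
  p <- list(baseline_gu = baseline_gu, onset_s = onset_s,
            amplitude_gu = amplitude_gu, time_to_peak_s = time_to_peak_s,
            shape_alpha = shape_alpha, retention_fraction = retention_fraction,
            washout_tau_s = washout_tau_s, noise_sd_gu = noise_sd_gu,
            bleach_rate_per_s = bleach_rate_per_s)
  bad <- c(
    if (baseline_gu < 0 || baseline_gu > 255) "baseline_gu in [0, 255]",
    if (onset_s < 0) "onset_s >= 0",
    if (amplitude_gu <= 0) "amplitude_gu > 0",
    if (time_to_peak_s <= 0) "time_to_peak_s > 0",
    if (shape_alpha <= 0) "shape_alpha > 0",
    if (retention_fraction < 0 || retention_fraction > 1) "retention_fraction in [0, 1]",
    if (washout_tau_s <= 0) "washout_tau_s > 0",
    if (noise_sd_gu < 0) "noise_sd_gu >= 0",
    if (bleach_rate_per_s < 0) "bleach_rate_per_s >= 0")
  if (length(bad)) {
    abort(paste0("invalid curve parameters: need ", paste(bad, collapse = ", ")),
          class = "fluotrack_validation_error")
  }
  structure(p, class = "curve_params")
}

#' @describeIn curve_params Evaluate the noiseless curve at times `t`
#'   (vectorized).
#' @param params A `curve_params` list.
#' @param t Times in seconds (>= 0).
#' @export
curve_value <- function(params, t) {
  p <- params
  out <- rep(p$baseline_gu, length(t))
  on <- t >= p$onset_s
  if (any(on)) {
    td <- t[on] - p$onset_s
    s <- td / p$time_to_peak_s
    gamma_term <- s^p$shape_alpha * exp(p$shape_alpha * (1 - s))
    retention <- 1 - exp(-td / p$washout_tau_s)
    signal <- p$amplitude_gu *
      ((1 - p$retention_fraction) * gamma_term +
         p$retention_fraction * retention) *
      exp(-p$bleach_rate_per_s * td)
    out[on] <- p$baseline_gu + signal
  }
  out
}

# Continuous-time maximum of the noiseless curve: coarse grid bracket, then
# golden-section refinement to `tol` seconds.
true_peak <- function(params, duration_s, tol = 1e-6) {
  p <- params
  if (p$retention_fraction == 0 && p$bleach_rate_per_s == 0) {
    tm <- p$onset_s + p$time_to_peak_s
    return(list(t_max = tm, f_max = p$baseline_gu + p$amplitude_gu))
  }
  grid <- seq(p$onset_s, duration_s, length.out = 20001)
  vals <- curve_value(p, grid)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  if (i == 1 || i == length(grid)) {
    return(list(t_max = grid[i], f_max = vals[i]))
  }
  opt <- optimize(function(t) curve_value(p, t), c(lo, hi), maximum = TRUE,
                  tol = tol)
  list(t_max = opt$maximum, f_max = opt$objective)
}

# First continuous-time upward crossing of `level` in [from, to].
true_crossing <- function(params, level, from, to, tol = 1e-6) {
  f <- function(t) curve_value(params, t) - level
  grid <- seq(from, to, length.out = 4001)
  vals <- f(grid)
  i <- which(vals >= 0)
  if (length(i) == 0) return(NA_real_)
  i <- i[1]
  if (i == 1) return(grid[1])
  uniroot(f, c(grid[i - 1], grid[i]), tol = tol)$root
}

# Analytic milestone truth of the noiseless curve, evaluated the same way
# the empirical profile is defined (times relative to t = 0, tracking
# length = last sample time).
true_profile <- function(params, fps, duration_s, rise_threshold_gu = 5) {
  p <- params
  t_last <- floor(duration_s * fps) / fps
  pk <- true_peak(p, t_last)
  lat_level <- p$baseline_gu + rise_threshold_gu
  t_lat <- true_crossing(p, lat_level, p$onset_s, pk$t_max)
  rise <- pk$f_max - lat_level
  time_to_rise <- pk$t_max - t_lat
  half_level <- lat_level + rise / 2
  t_half_abs <- true_crossing(p, half_level, t_lat, pk$t_max)
  t100 <- pk$t_max + 100
  complete <- t_last >= t100
  f100 <- if (complete) curve_value(p, t100) else NA_real_
  final <- curve_value(p, t_last)
  samples <- curve_value(p, seq(0, t_last, by = 1 / fps))
  tibble::tibble(
    baseline_gu = p$baseline_gu,
    latency_end_intensity_gu = lat_level,
    latency_end_time_s = t_lat,
    f_max_gu = pk$f_max, rise_gu = rise, t_max_s = pk$t_max,
    time_to_rise_s = time_to_rise,
    upslope_gradient_gu_per_s = rise / time_to_rise,
    f_half_gu = rise / 2,
    t_half_s = t_half_abs - t_lat,
    t_half_over_t_max = (t_half_abs - t_lat) / pk$t_max,
    t100_s = t100,
    f100_gu = f100,
    fall100_gu = if (complete) pk$f_max - f100 else NA_real_,
    downslope100_gu_per_s = if (complete) (pk$f_max - f100) / 100 else NA_real_,
    tracking_length_s = t_last,
    time_after_tmax_s = t_last - pk$t_max,
    final_intensity_gu = final,
    downslope_gradient_gu_per_s = (pk$f_max - final) / (t_last - pk$t_max),
    kurtosis = sample_excess_kurtosis(samples),
    skew = sample_skewness(samples),
    complete = complete)
}

#' Simulate one intensity trace with known milestone truth
#'
#' Samples the parametric curve at `fps` over `[0, duration_s]`, adds
#' i.i.d. Gaussian noise (`noise_sd_gu`), clips to the 8-bit range, and
#' returns the trace alongside the analytic milestone profile of the
#' noiseless curve (peak by closed form or golden-section refinement,
#' level crossings by root-finding at 1e-6 s).
#'
#' @param params A [curve_params()].
#' @param fps Sampling rate (frames/second).
#' @param duration_s Trace duration; must cover `onset_s + time_to_peak_s`.
#' @param seed RNG seed for the noise (the caller's RNG state is
#'   preserved).
#' @param roi_label,tissue_class Metadata for the generated trace.
#' @return List with `trace` (an [intensity_trace()]) and `truth` (one-row
#'   tibble of analytic milestones). Clipping affecting more than 5% of
#'   samples triggers a warning (the analytic truth is then compromised).
#' @export
simulate_trace <- function(params, fps = 30, duration_s = 600, seed = 1,
                           roi_label = "sim", tissue_class = NA_character_) {
  p <- params
  if (duration_s < p$onset_s + p$time_to_peak_s) {
    abort("duration_s must cover onset_s + time_to_peak_s",
          class = "fluotrack_validation_error")
  }
  t <- seq(0, duration_s, by = 1 / fps)
  v <- curve_value(p, t)
  if (p$noise_sd_gu > 0) {
    v <- v + with_seed(seed, rnorm(length(t), 0, p$noise_sd_gu))
  }
  clipped <- v < 0 | v > 255
  if (mean(clipped) > 0.05) {
    warn(sprintf("%.1f%% of samples clipped to [0, 255]; analytic truth compromised",
                 100 * mean(clipped)))
  }
  v <- pmin(pmax(v, 0), 255)
  list(trace = intensity_trace(t, v, roi_label = roi_label,
                               tissue_class = tissue_class,
                               fps_effective = fps),
       truth = true_profile(p, fps, duration_s))
}

#' Group presets for synthetic cohorts
#'
#' Default kinetic regimes emulating the qualitative clinical contrasts:
#' malignant lesions peak late (time-to-peak such that the peak falls near
#' 190 s), rise with a shallow gradient and retain dye (high retention
#' fraction, hence a small 100-s fall), while benign lesions (peak near
#' 84 s) and normal mucosa (near 73 s) wash in briskly and clear.
#'
#' @return Named list of [curve_params()] (`benign`, `cancer`, `control`).
#' @export
cohort_presets <- function() {
  list(
    benign = curve_params(baseline_gu = 10, onset_s = 10, amplitude_gu = 145,
                          time_to_peak_s = 72.7, shape_alpha = 2,
                          retention_fraction = 0.10, washout_tau_s = 45),
    cancer = curve_params(baseline_gu = 10, onset_s = 10, amplitude_gu = 130,
                          time_to_peak_s = 173, shape_alpha = 2,
                          retention_fraction = 0.35, washout_tau_s = 60),
    control = curve_params(baseline_gu = 10, onset_s = 10, amplitude_gu = 135,
                           time_to_peak_s = 61.8, shape_alpha = 2,
                           retention_fraction = 0.10, washout_tau_s = 45))
}

#' Simulate a labelled cohort of traces
#'
#' Per-subject curve parameters are drawn around the group presets with
#' multiplicative lognormal dispersion (`sdlog = dispersion`) on amplitude
#' and time-to-peak, and the retention fraction jittered on the same scale
#' then clamped to `[0, 0.95]`. `dispersion = 0` with zero noise
#' reproduces the presets exactly. Fully reproducible by `seed`.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param fps,duration_s Sampling regime (defaults 30 fps, 600 s — the
#'   scale of continuous endoscopic recordings).
#' @param seed RNG seed.
#' @param presets Named list of group [curve_params()].
#' @param dispersion Lognormal sdlog of between-subject variation.
#' @param noise_sd_gu Measurement noise SD (g.u.).
#' @return List with `traces` (list of intensity traces, tissue class set
#'   to the group name) and `truth` (tibble of per-subject analytic
#'   milestones with `group` and `subject` columns).
#' @export
simulate_cohort <- function(n_per_group = 20, fps = 30, duration_s = 600,
                            seed = 1, presets = cohort_presets(),
                            dispersion = 0.25, noise_sd_gu = 2) {
  stopifnot(n_per_group >= 1)
  draws <- with_seed(seed, {
    purrr::map(names(presets), function(g) {
      purrr::map(seq_len(n_per_group), function(i) {
        p <- presets[[g]]
        amp <- p$amplitude_gu * rlnorm(1, 0, dispersion)
        tp <- p$time_to_peak_s * rlnorm(1, 0, dispersion)
        ret <- min(max(p$retention_fraction * rlnorm(1, 0, dispersion), 0), 0.95)
        sub_seed <- sample.int(2^31 - 1, 1)
        list(group = g, subject = i, sub_seed = sub_seed,
             params = curve_params(
               baseline_gu = p$baseline_gu, onset_s = p$onset_s,
               amplitude_gu = min(amp, 243), time_to_peak_s = tp,
               shape_alpha = p$shape_alpha, retention_fraction = ret,
               washout_tau_s = p$washout_tau_s, noise_sd_gu = noise_sd_gu,
               bleach_rate_per_s = p$bleach_rate_per_s))
      })
    })
  })
  draws <- purrr::flatten(draws)
  sims <- purrr::map(draws, function(d) {
    simulate_trace(d$params, fps, duration_s, seed = d$sub_seed,
                   roi_label = sprintf("%s_%02d", d$group, d$subject),
                   tissue_class = d$group)
  })
  truth <- purrr::map2_dfr(draws, sims, function(d, s) {
    dplyr::bind_cols(tibble::tibble(group = d$group, subject = d$subject),
                     s$truth)
  })
  list(traces = purrr::map(sims, "trace"), truth = truth)
}

#' Scene description for synthetic dual-channel video
#'
#' @param width,height Frame size in pixels.
#' @param fps Frame rate.
#' @param duration_s Scene length in seconds.
#' @param lesion_polygon,control_polygon Disjoint region polygons in
#'   frame-0 coordinates.
#' @param lesion_params,control_params [curve_params()] driving each
#'   region's NIR intensity.
#' @param camera_path `n_frames x 4` matrix (columns scale, theta_rad, tx,
#'   ty): the similarity transform mapping frame-0 coordinates to frame-k
#'   coordinates. Defaults to the identity (static camera); see
#'   [smooth_camera_path()].
#' @param occlusions List of `c(start_frame, end_frame)` intervals
#'   (0-based, inclusive) rendered as full-field uniform grey in both
#'   channels.
#' @param nir_background_gu Dim NIR background level.
#' @param noise_sd_gu Per-pixel Gaussian noise SD in the NIR channel.
#' @param texture_seed Seed of the white-light background texture.
#' @param seed Master seed for the per-frame noise.
#' @return A validated `scene_config`.
#' @export
scene_config <- function(width = 320, height = 240, fps = 30, duration_s = 120,
                         lesion_polygon, lesion_params,
                         control_polygon, control_params,
                         camera_path = NULL, occlusions = list(),
                         nir_background_gu = 5, noise_sd_gu = 0,
                         texture_seed = 42, seed = 1) {
  n_frames <- as.integer(floor(duration_s * fps))
  if (is.null(camera_path)) {
    camera_path <- cbind(scale = rep(1, n_frames), theta = 0, tx = 0, ty = 0)
  }
  stopifnot(nrow(camera_path) >= n_frames)
  lesion_polygon <- validate_polygon(lesion_polygon)
  control_polygon <- validate_polygon(control_polygon)
  if ((polygon_iou(lesion_polygon, control_polygon) %||% 0) > 0) {
    abort("lesion and control polygons must be disjoint",
          class = "fluotrack_validation_error")
  }
  occ_frames <- integer(0)
  for (o in occlusions) occ_frames <- c(occ_frames, seq(o[1], o[2]))
  # every polygon must stay in frame on every non-occluded frame
  for (k in seq(0L, n_frames - 1L)) {
    if (k %in% occ_frames) next
    tf <- similarity_params(camera_path[k + 1, 1], camera_path[k + 1, 2],
                            camera_path[k + 1, 3], camera_path[k + 1, 4])
    for (poly in list(lesion_polygon, control_polygon)) {
      wp <- apply_similarity(tf, poly)
      if (any(wp[, 1] < 0 | wp[, 1] > width - 1 | wp[, 2] < 0 | wp[, 2] > height - 1)) {
        abort(sprintf("polygon leaves the frame at non-occluded frame %d", k),
              class = "fluotrack_validation_error")
      }
    }
  }
  structure(list(width = width, height = height, fps = fps,
                 duration_s = duration_s, n_frames = n_frames,
                 lesion_polygon = lesion_polygon, lesion_params = lesion_params,
                 control_polygon = control_polygon, control_params = control_params,
                 camera_path = camera_path, occlusions = occlusions,
                 occ_frames = occ_frames,
                 nir_background_gu = nir_background_gu,
                 noise_sd_gu = noise_sd_gu, texture_seed = texture_seed,
                 seed = seed),
            class = "scene_config")
}

#' Smooth sinusoidal camera path
#'
#' Endoscope-like slow drift: sinusoidal translation, gentle rotation and
#' breathing scale, all smooth in time.
#'
#' @param n_frames Number of frames.
#' @param fps Frame rate.
#' @param amp_px Translation amplitude (pixels).
#' @param amp_deg Rotation amplitude (degrees).
#' @param amp_scale Fractional scale amplitude.
#' @param period_s Oscillation period (s).
#' @return `n_frames x 4` matrix (scale, theta, tx, ty).
#' @export
smooth_camera_path <- function(n_frames, fps, amp_px = 6, amp_deg = 2,
                               amp_scale = 0.01, period_s = 40) {
  t <- seq(0, by = 1 / fps, length.out = n_frames)
  w <- 2 * pi / period_s
  cbind(scale = 1 + amp_scale * sin(w * t),
        theta = amp_deg * pi / 180 * sin(w * t * 0.7),
        tx = amp_px * sin(w * t),
        ty = 0.6 * amp_px * (1 - cos(w * t * 1.3)))
}

# 3x3 box blur of a matrix (reflective edges via shrinking windows).
box_blur <- function(m) {
  m <- apply(m, 2, moving_average, w = 3)
  t(apply(t(m), 2, moving_average, w = 3))
}

#' Render a ground-truthed synthetic dual-channel video
#'
#' The white-light channel is a fixed random texture (seeded, then lightly
#' blurred so it carries trackable corner structure) warped through the
#' per-frame camera transform; the NIR channel is a dim background with
#' the lesion and control polygons filled at their parametric curve value,
#' plus optional per-pixel Gaussian noise. Occluded frames are full-field
#' uniform grey in both channels. Frames are rendered lazily and
#' deterministically (per-frame seeds derived from the scene seed), so a
#' stream can be traversed repeatedly with identical results.
#'
#' @param scene A [scene_config()].
#' @return List with `stream` (a `frame_stream`), and ground truth:
#'   `polygons` (per-frame list per region, `NULL` on occluded frames),
#'   `traces` (tibble of true per-frame region intensities),
#'   `labels`, `occ_frames`, and the scene itself.
#' @export
simulate_video <- function(scene) {
  stopifnot(inherits(scene, "scene_config"))
  w <- scene$width; h <- scene$height
  margin <- 40L
  texture <- with_seed(scene$texture_seed, {
    tx <- matrix(runif((h + 2 * margin) * (w + 2 * margin), 0, 1),
                 h + 2 * margin, w + 2 * margin)
    40 + 180 * box_blur(tx)
  })
  n <- scene$n_frames
  occ <- scene$occ_frames
  regions <- list(lesion = list(poly = scene$lesion_polygon,
                                params = scene$lesion_params),
                  control = list(poly = scene$control_polygon,
                                 params = scene$control_params))
  tf_for <- function(k) {
    similarity_params(scene$camera_path[k + 1, 1], scene$camera_path[k + 1, 2],
                      scene$camera_path[k + 1, 3], scene$camera_path[k + 1, 4])
  }
  true_polys <- purrr::map(names(regions), function(nm) {
    purrr::map(seq(0L, n - 1L), function(k) {
      if (k %in% occ) return(NULL)
      apply_similarity(tf_for(k), regions[[nm]]$poly)
    })
  })
  names(true_polys) <- names(regions)
  times <- seq(0L, n - 1L) / scene$fps
  true_traces <- purrr::map_dfr(names(regions), function(nm) {
    tibble::tibble(region = nm, frame = seq(0L, n - 1L), time_s = times,
                   intensity_gu = curve_value(regions[[nm]]$params, times),
                   occluded = seq(0L, n - 1L) %in% occ)
  })
  frame_seed <- function(k) (scene$seed %% 100000L) * 20011L + k

  rgb_fun <- function(k) {
    if (k %in% occ) {
      return(array(128, dim = c(h, w, 3)))
    }
    inv <- invert_similarity(tf_for(k))
    grey <- cpp_similarity_sample(texture, h, w, inv[1], inv[2],
                                  inv[3] + margin, inv[4] + margin)
    array(grey, dim = c(h, w, 3))
  }
  nir_fun <- function(k) {
    if (k %in% occ) {
      return(matrix(128, h, w))
    }
    img <- matrix(scene$nir_background_gu, h, w)
    t_k <- k / scene$fps
    for (nm in names(regions)) {
      poly <- true_polys[[nm]][[k + 1]]
      mask <- cpp_polygon_mask(h, w, poly[, 1], poly[, 2])
      img[mask] <- curve_value(regions[[nm]]$params, t_k)
    }
    if (scene$noise_sd_gu > 0) {
      img <- img + with_seed(frame_seed(k),
                             matrix(rnorm(h * w, 0, scene$noise_sd_gu), h, w))
    }
    pmin(pmax(img, 0), 255)
  }
  stream <- stream_from_frames(rgb_fun, nir_fun, scene$fps, n_frames = n)
  list(stream = stream, polygons = true_polys, traces = true_traces,
       labels = c(lesion = "tumour", control = "control"),
       occ_frames = occ, scene = scene)
}
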