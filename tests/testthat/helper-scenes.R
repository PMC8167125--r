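# Shared fixture builders (everything generated in code at test time).

# Smooth random texture with plenty of corner structure.
make_texture <- function(h, w, seed = 3) {
  withr::with_seed(seed, {
    m <- matrix(runif(h * w), h, w)
    sm <- apply(m, 2, function(col) stats::filter(col, rep(1 / 3, 3), sides = 2))
    sm <- t(apply(t(sm), 2, function(col) stats::filter(col, rep(1 / 3, 3), sides = 2)))
    sm[is.na(sm)] <- 0.5
    40 + 180 * sm
  })
}

as_rgb <- function(grey) array(grey, dim = c(dim(grey), 3))

# Checkerboard with a horizontal contrast ramp so corner responses differ.
make_checkerboard <- function(size = 100, square = 25) {
  xs <- matrix(rep(0:(size - 1), each = size), size, size)
  ys <- matrix(rep(0:(size - 1), size), size, size)
  checker <- ((xs %/% square + ys %/% square) %% 2) * 200
  checker * (0.5 + xs / (2 * size)) + 20
}

checkerboard_corners <- function(size = 100, square = 25) {
  pos <- seq(square, size - square, by = square)
  expand.grid(x = pos, y = pos)
}

default_lesion_poly <- function() cbind(c(60, 120, 120, 60), c(60, 60, 110, 110))
default_control_poly <- function() cbind(c(190, 250, 250, 190), c(120, 120, 170, 170))

quick_params <- function(...) {
  args <- utils::modifyList(
    list(baseline_gu = 10, onset_s = 2, amplitude_gu = 140,
         time_to_peak_s = 5, shape_alpha = 2, retention_fraction = 0.1,
         washout_tau_s = 20),
    list(...))
  do.call(curve_params, args)
}

make_scene <- function(duration_s = 5, fps = 30, moving = TRUE,
                       noise_sd_gu = 0, occlusions = list(), seed = 7,
                       width = 320, height = 240) {
  n <- as.integer(duration_s * fps)
  path <- if (moving) smooth_camera_path(n, fps) else NULL
  scene_config(width = width, height = height, fps = fps,
               duration_s = duration_s,
               lesion_polygon = default_lesion_poly(),
               lesion_params = quick_params(),
               control_polygon = default_control_poly(),
               control_params = quick_params(amplitude_gu = 120,
                                             time_to_peak_s = 4),
               camera_path = path, occlusions = occlusions,
               noise_sd_gu = noise_sd_gu, seed = seed)
}

scene_annotations <- function(both = TRUE) {
  out <- roi_annotation("lesion", "tumour", 0, default_lesion_poly())
  if (both) {
    out <- dplyr::bind_rows(out, roi_annotation("control", "control", 0,
                                                default_control_poly()))
  }
  out
}

mean_tracking_iou <- function(truth_polys, result) {
  ious <- vapply(seq_along(truth_polys), function(i) {
    tp <- truth_polys[[i]]
    pp <- result$polygons[[i]]
    if (is.null(tp) || is.null(pp)) NA_real_ else polygon_iou(tp, pp)
  }, numeric(1))
  mean(ious, na.rm = TRUE)
}

# Two-regime point-trace cohort for the grouping tests; effect in [0, 1]
# linearly interpolates the control regime toward the cancer regime.
# Points within a class carry lognormal parameter dispersion (different
# tissue positions) on top of the per-sample measurement noise.
two_regime_points <- function(n_per_class = 50, effect = 1, noise_sd = 2,
                              fps = 10, duration_s = 400, seed0 = 500,
                              dispersion = 0.15) {
  ps <- cohort_presets()
  blend <- function(field) {
    ps$control[[field]] + effect * (ps$cancer[[field]] - ps$control[[field]])
  }
  mk <- function(base, label, offset) {
    lapply(seq_len(n_per_class), function(i) {
      params <- withr::with_seed(seed0 + offset + i, curve_params(
        baseline_gu = base$baseline_gu, onset_s = base$onset_s,
        amplitude_gu = base$amplitude_gu * rlnorm(1, 0, dispersion),
        time_to_peak_s = base$time_to_peak_s * rlnorm(1, 0, dispersion),
        shape_alpha = base$shape_alpha,
        retention_fraction = min(base$retention_fraction * rlnorm(1, 0, dispersion), 0.95),
        washout_tau_s = base$washout_tau_s, noise_sd_gu = noise_sd))
      simulate_trace(params, fps = fps, duration_s = duration_s,
                     seed = seed0 + offset + i + 1L, tissue_class = label)$trace
    })
  }
  tumour_base <- list(baseline_gu = 10, onset_s = 10,
                      amplitude_gu = blend("amplitude_gu"),
                      time_to_peak_s = blend("time_to_peak_s"),
                      shape_alpha = 2,
                      retention_fraction = blend("retention_fraction"),
                      washout_tau_s = blend("washout_tau_s"))
  control_base <- list(baseline_gu = 10, onset_s = 10,
                       amplitude_gu = ps$control$amplitude_gu,
                       time_to_peak_s = ps$control$time_to_peak_s,
                       shape_alpha = 2,
                       retention_fraction = ps$control$retention_fraction,
                       washout_tau_s = ps$control$washout_tau_s)
  pts <- c(mk(tumour_base, "tumour", 0), mk(control_base, "control", 100000))
  names(pts) <- sprintf("p%03d", seq_along(pts))
  pts
}
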