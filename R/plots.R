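#' Plot an intensity trace
#'
#' Fluorescence intensity versus time; gap intervals are left blank.
#'
#' @param object An [intensity_trace()].
#' @param smoothing_window_s Optional overlay of the smoothed curve used
#'   for milestone detection (0 = none).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_trace <- function(object, smoothing_window_s = 0, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$intensity_gu)) +
    ggplot2::geom_line(colour = "grey40", na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "fluorescence intensity (g.u.)",
                  title = attr(object, "roi_label")) +
    ggplot2::theme_minimal()
  if (smoothing_window_s > 0) {
    s <- trace_samples(object)
    fps <- trace_meta(object)$fps_effective
    sm <- moving_average(s$v, smoothing_width(smoothing_window_s, fps))
    p <- p + ggplot2::geom_line(data = tibble::tibble(time_s = s$t, intensity_gu = sm),
                                colour = "firebrick")
  }
  p
}

#' Plot a trace with its kinetic milestones
#'
#' Overlays the latency end, peak and 100-s washout flag on the trace.
#'
#' @param trace An intensity trace.
#' @param profile The matching [compute_profile()] row (computed if
#'   missing).
#' @param ... Passed to [compute_profile()] when `profile` is missing.
#' @return A ggplot.
#' @export
plot_profile <- function(trace, profile = NULL, ...) {
  if (is.null(profile)) profile <- compute_profile(trace, ...)
  marks <- tibble::tibble(
    milestone = c("latency end", "peak", "washout flag (t_max + 100 s)"),
    time_s = c(profile$latency_end_time_s, profile$t_max_s, profile$t100_s),
    intensity_gu = c(profile$latency_end_intensity_gu, profile$f_max_gu,
                     profile$f100_gu))
  marks <- marks[!is.na(marks$time_s) & !is.na(marks$intensity_gu), ]
  autoplot.intensity_trace(trace) +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(colour = .data$milestone), size = 3) +
    ggplot2::labs(colour = NULL)
}

#' Plot group mean fluorescence curves
#'
#' One mean curve per tissue class, aligned on the latency end, with the
#' logarithmic trend (dotted) optionally overlaid.
#'
#' @param curves Output of [group_mean_curves()].
#' @param log_fit Overlay `a * ln(t + 1) + b` fits per class?
#' @return A ggplot.
#' @export
plot_group_curves <- function(curves, log_fit = TRUE) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time_s,
                                            y = .data$mean_intensity_gu,
                                            colour = .data$tissue_class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from latency end (s)",
                  y = "mean fluorescence intensity (g.u.)",
                  colour = "tissue") +
    ggplot2::theme_minimal()
  if (log_fit) {
    fits <- curves |>
      dplyr::group_by(.data$tissue_class) |>
      dplyr::group_modify(function(d, g) {
        x <- log(d$time_s + 1)
        m <- lm(d$mean_intensity_gu ~ x)
        tibble::tibble(time_s = d$time_s,
                       fit = unname(coef(m)[1]) + unname(coef(m)[2]) * x)
      }) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_line(data = fits,
                                ggplot2::aes(y = .data$fit), linetype = "dotted")
  }
  p
}

#' @describeIn run_tracking Plot the tracked centroid path; gap frames
#'   appear as breaks.
#' @param object A `track_result`.
#' @export
autoplot.track_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$centroid_x, colour = "centroid x"),
                       na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$centroid_y, colour = "centroid y"),
                       na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "pixels", colour = NULL,
                  title = sprintf("ROI '%s' (%d gap(s), %.2f s censored)",
                                  object$roi_label, nrow(object$gaps),
                                  object$censored_s)) +
    ggplot2::theme_minimal()
}

#' @describeIn knn_group Scatter of the first two principal components of
#'   the signatures, coloured by assigned cluster.
#' @param object A `grouping_result`.
#' @param signatures The [build_signatures()] tibble the grouping was run
#'   on.
#' @export
autoplot.grouping_result <- function(object, signatures, ...) {
  X <- signature_matrix(signatures)
  pc <- stats::prcomp(X, rank. = 2)
  df <- tibble::tibble(pc1 = pc$x[, 1], pc2 = pc$x[, 2],
                       assigned = object$assignments$assigned,
                       held_out = object$assignments$held_out)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   colour = .data$assigned,
                                   shape = .data$held_out)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "cluster",
                  shape = "held out") +
    ggplot2::theme_minimal()
}

#' Plot a group comparison table
#'
#' Group mean with SD error bars per kinetic variable (free scales).
#'
#' @param table A [build_group_table()] result.
#' @param variables Subset of variables to show (default: all rows).
#' @return A ggplot.
#' @export
plot_group_table <- function(table, variables = table$variable) {
  groups <- sub("^mean_", "", grep("^mean_", names(table), value = TRUE))
  long <- purrr::map_dfr(groups, function(g) {
    tibble::tibble(variable = table$variable,
                   group = g,
                   mean = table[[paste0("mean_", g)]],
                   sd = table[[paste0("sd_", g)]])
  }) |>
    dplyr::filter(.data$variable %in% variables)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "mean +/- SD") +
    ggplot2::theme_minimal()
}
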