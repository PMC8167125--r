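#' Published reference group summaries
#'
#' Per-group mean / SD / n of every kinetic milestone variable as printed
#' by the originating clinical fluorescence-angiography study, for both
#' its measurement regimes: `"manual"` (frame-by-frame measurement at
#' 1 fps; benign n = 5, cancer n = 3, control n = 8) and `"tracker"`
#' (automated 30 fps tracking; n = 11 / 9 / 20). These published summary
#' values serve as input data for consistency checks of the milestone
#' definitions — they are not recomputable from raw data, which were
#' never deposited.
#'
#' @param table `"tracker"`, `"manual"` or `"both"`.
#' @return Tibble: `table`, `variable`, `group`, `mean`, `sd`, `n`.
#' @export
reference_group_summaries <- function(table = c("both", "tracker", "manual")) {
  table <- match.arg(table)
  path <- system.file("extdata", "reference_group_summaries.csv",
                      package = "fluotrack", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (table != "both") df <- df[df$table == table, ]
  df
}

#' Milestone identities applied to summary values
#'
#' The derived milestone variables are exact arithmetic functions of the
#' primitive ones: `rise = f_max - latency intensity`, `f_half = rise / 2`,
#' `time_to_rise = t_max - latency time`, `t100 = t_max + 100`,
#' `fall100 = f_max - f100`, `downslope100 = fall100 / 100`,
#' `time_after_tmax = tracking_length - t_max`. Applying them to per-group
#' mean values must reproduce the reported derived means (means are linear
#' in these identities), which pins down the definitions implemented in
#' [compute_profile()]. This function computes each derived variable from
#' the primitive summary means and pairs it with the reported value.
#'
#' @param summaries A tibble like [reference_group_summaries()] (columns
#'   `table`, `variable`, `group`, `mean`).
#' @return Tibble: `table`, `group`, `identity`, `computed`, `reported`,
#'   `abs_diff`.
#' @export
milestone_identities <- function(summaries = reference_group_summaries()) {
  wide <- summaries |>
    dplyr::select("table", "variable", "group", "mean") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "mean")
  wide |>
    dplyr::rowwise() |>
    dplyr::reframe(
      table = .data$table, group = .data$group,
      identity = c("rise_gu", "f_half_gu", "time_to_rise_s", "t100_s",
                   "fall100_gu", "downslope100_gu_per_s", "time_after_tmax_s"),
      computed = c(.data$f_max_gu - .data$latency_end_intensity_gu,
                   (.data$f_max_gu - .data$latency_end_intensity_gu) / 2,
                   .data$t_max_s - .data$latency_end_time_s,
                   .data$t_max_s + 100,
                   .data$f_max_gu - .data$f100_gu,
                   (.data$f_max_gu - .data$f100_gu) / 100,
                   .data$tracking_length_s - .data$t_max_s),
      reported = c(.data$rise_gu, .data$f_half_gu, .data$time_to_rise_s,
                   .data$t100_s, .data$fall100_gu,
                   .data$downslope100_gu_per_s, .data$time_after_tmax_s)) |>
    dplyr::mutate(abs_diff = abs(.data$computed - .data$reported))
}
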