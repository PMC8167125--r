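#' Nonparametric two-sample and paired tests
#'
#' Thin, tibble-returning wrappers around the standard rank tests with the
#' conventions used throughout the package: two-sided p-values, exact
#' distributions on small untied samples (total n <= 12), and the
#' normal approximation with tie correction otherwise.
#'
#' @name rank-tests
NULL

#' @describeIn rank-tests Mann-Whitney U for two independent samples. `U`
#'   is reported for `sample_a` (number of (a, b) pairs with a > b, ties
#'   counting half).
#' @param sample_a,sample_b Numeric samples (non-empty).
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    abort("both samples must be non-empty", class = "fluotrack_validation_error")
  }
  ties <- any(duplicated(c(sample_a, sample_b)))
  exact <- (length(sample_a) + length(sample_b)) <= 12 && !ties
  res <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = exact, correct = !exact))
  tibble::tibble(U = unname(res$statistic), p_value = res$p.value,
                 exact = exact)
}

#' @describeIn rank-tests Wilcoxon signed-rank test on paired samples.
#'   Zero differences are dropped by convention; if every difference is
#'   zero the test is degenerate and p = 1 is returned with
#'   `all_zero = TRUE`. Exact distribution for <= 12 non-zero pairs
#'   without ties.
#' @param paired_a,paired_b Paired numeric vectors of equal length.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b) || length(paired_a) < 1) {
    abort("paired samples must have equal length >= 1",
          class = "fluotrack_validation_error")
  }
  d <- paired_a - paired_b
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(tibble::tibble(W = 0, p_value = 1, exact = TRUE, all_zero = TRUE))
  }
  ties <- any(duplicated(abs(nz)))
  exact <- length(nz) <= 12 && !ties
  res <- suppressWarnings(
    wilcox.test(paired_a, paired_b, paired = TRUE, exact = exact,
                correct = !exact))
  tibble::tibble(W = unname(res$statistic), p_value = res$p.value,
                 exact = exact, all_zero = FALSE)
}

#' @describeIn rank-tests Kruskal-Wallis H across two or more groups, with
#'   tie correction; p from the chi-squared distribution on
#'   `length(groups) - 1` degrees of freedom. All-identical values give
#'   H = 0, p = 1.
#' @param groups List of numeric samples (each non-empty).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort(">= 2 non-empty groups required", class = "fluotrack_validation_error")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1) {
    return(tibble::tibble(H = 0, df = length(groups) - 1L, p_value = 1))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  res <- kruskal.test(values, g)
  tibble::tibble(H = unname(res$statistic), df = unname(res$parameter),
                 p_value = res$p.value)
}

#' Per-group summary and significance table of kinetic variables
#'
#' Builds the standard comparison table: one row per kinetic milestone
#' variable with per-group mean, sample standard deviation (n - 1
#' denominator) and n, the Kruskal-Wallis p across all groups, the
#' pairwise Mann-Whitney p-values, and a significance marker at p < 0.05.
#' Incomplete profiles contribute only to the variables they define
#' (per-variable n may therefore drop below the group size; such rows are
#' flagged in `footnote`). With a single profile in a group the SD is
#' undefined and reported as 0 with a flag, and the tests for that row
#' are skipped. No multiple-testing correction is applied by default
#' (`p_adjust = "BH"` adds Benjamini-Hochberg-adjusted columns). The
#' table is invariant to the input row order.
#'
#' @param profiles Tibble of [compute_profile()] rows (bind them with
#'   `dplyr::bind_rows()`).
#' @param group Column name holding the group membership (default
#'   `"tissue_class"`).
#' @param group_levels Column order of the groups (defaults to
#'   benign / cancer / control when present).
#' @param variables Variables to tabulate (default [kinetic_variables()]).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A `group_table` tibble: `variable`, then per group
#'   `mean_<g>`, `sd_<g>`, `n_<g>`, then `kruskal_wallis_p`, one
#'   `p_<a>_vs_<b>` per pair, `significant`, `footnote`.
#' @export
build_group_table <- function(profiles, group = "tissue_class",
                              group_levels = NULL,
                              variables = kinetic_variables(),
                              p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(group %in% names(profiles))
  gvals <- profiles[[group]]
  if (is.null(group_levels)) {
    canonical <- c("benign", "cancer", "control", "tumour")
    present <- unique(gvals)
    group_levels <- c(intersect(canonical, present),
                      sort(setdiff(present, canonical)))
  }
  profiles <- profiles[order(match(gvals, group_levels)), ]
  gvals <- profiles[[group]]
  pairs <- if (length(group_levels) >= 2) utils::combn(group_levels, 2, simplify = FALSE) else list()
  rows <- purrr::map_dfr(variables, function(v) {
    if (!v %in% names(profiles)) return(NULL)
    samples <- purrr::map(group_levels, function(g) {
      x <- profiles[[v]][gvals == g]
      x[!is.na(x)]
    })
    names(samples) <- group_levels
    row <- tibble::tibble(variable = v)
    footnotes <- character(0)
    for (g in group_levels) {
      x <- samples[[g]]
      row[[paste0("mean_", g)]] <- if (length(x)) mean(x) else NA_real_
      row[[paste0("sd_", g)]] <- if (length(x) >= 2) sd(x) else 0
      row[[paste0("n_", g)]] <- length(x)
      if (length(x) == 1) footnotes <- c(footnotes, paste0("sd undefined (n=1): ", g))
      if (length(x) == 0) footnotes <- c(footnotes, paste0("empty group: ", g))
      if (length(x) > 0 && length(x) < sum(gvals == g)) {
        footnotes <- c(footnotes, paste0("partial profiles dropped: ", g))
      }
    }
    testable <- all(lengths(samples) >= 2)
    row$kruskal_wallis_p <- if (testable && length(samples) >= 2) {
      kruskal_wallis(samples)$p_value
    } else {
      NA_real_
    }
    for (pr in pairs) {
      nm <- paste0("p_", pr[1], "_vs_", pr[2])
      row[[nm]] <- if (length(samples[[pr[1]]]) >= 2 && length(samples[[pr[2]]]) >= 2) {
        mann_whitney_u(samples[[pr[1]]], samples[[pr[2]]])$p_value
      } else {
        NA_real_
      }
    }
    row$footnote <- if (length(footnotes)) paste(unique(footnotes), collapse = "; ") else NA_character_
    row
  })
  if (p_adjust == "BH") {
    pcols <- grep("^(kruskal_wallis_p|p_)", names(rows), value = TRUE)
    for (pc in pcols) {
      rows[[paste0(pc, "_adj")]] <- stats::p.adjust(rows[[pc]], method = "BH")
    }
  }
  rows$significant <- !is.na(rows$kruskal_wallis_p) & rows$kruskal_wallis_p < 0.05
  class(rows) <- c("group_table", class(rows))
  rows
}
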