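#' Build dynamic signatures for tracked points
#'
#' Each tracked point contributes a fixed-length feature vector: its
#' intensity course linearly resampled onto `n_resample` points over the
#' common post-latency horizon (so curves are aligned on inflow start),
#' plus three kinetic summary features (`t_max_s`, `rise_gu`,
#' `downslope100_gu_per_s`). Every feature is then standardized (z-score)
#' across points. Points whose trace is too short for a complete profile
#' (no detectable latency end, or ending before the 100-s washout flag)
#' are excluded and listed in the `excluded` attribute.
#'
#' @param point_traces Named list of intensity traces, one per tracked
#'   point; each trace's `tissue_class` metadata is the seed label from
#'   the ROI the point was detected in.
#' @param n_resample Number of resampled intensity features (default 100).
#' @inheritParams detect_latency_end
#' @return A `point_signatures` tibble: `point_id`, `seed_label`, then the
#'   standardized feature columns; the unstandardized feature matrix and
#'   excluded ids ride along as attributes.
#' @export
build_signatures <- function(point_traces, n_resample = 100,
                             rise_threshold_gu = 5, baseline_window_s = 3,
                             smoothing_window_s = 1) {
  ids <- names(point_traces) %||% as.character(seq_along(point_traces))
  prepped <- purrr::imap(point_traces, function(tr, i) {
    lat <- tryCatch(
      detect_latency_end(tr, rise_threshold_gu, baseline_window_s,
                         smoothing_window_s),
      fluotrack_no_inflow = function(e) NULL,
      fluotrack_validation_error = function(e) NULL)
    if (is.null(lat)) return(NULL)
    prof <- tryCatch(
      compute_profile(tr, smoothing_window_s, rise_threshold_gu,
                      baseline_window_s),
      error = function(e) NULL)
    if (is.null(prof) || !isTRUE(prof$complete)) return(NULL)
    s <- trace_samples(tr)
    list(t = s$t - lat$time_s, v = s$v,
         label = trace_meta(tr)$tissue_class,
         t_max = prof$t_max_s, rise = prof$rise_gu,
         downslope100 = prof$downslope100_gu_per_s)
  })
  keep <- !purrr::map_lgl(prepped, is.null)
  excluded <- ids[!keep]
  if (length(excluded)) {
    warn(sprintf("%d point trace(s) excluded (incomplete profile): %s",
                 length(excluded), paste(head(excluded, 5), collapse = ", ")))
  }
  prepped <- prepped[keep]
  ids <- ids[keep]
  if (length(prepped) == 0) {
    abort("no usable point traces", class = "fluotrack_validation_error")
  }
  horizon <- min(purrr::map_dbl(prepped, ~ max(.x$t)))
  grid <- seq(0, horizon, length.out = n_resample)
  feats <- t(vapply(prepped, function(a) {
    c(approx(a$t, a$v, xout = grid)$y, a$t_max, a$rise, a$downslope100)
  }, numeric(n_resample + 3)))
  colnames(feats) <- c(sprintf("fi_%03d", seq_len(n_resample)),
                       "t_max_s", "rise_gu", "downslope100_gu_per_s")
  zs <- scale(feats)
  zs[, attr(zs, "scaled:scale") == 0] <- 0  # constant features carry no signal
  out <- dplyr::bind_cols(
    tibble::tibble(point_id = ids,
                   seed_label = purrr::map_chr(prepped, "label")),
    tibble::as_tibble(as.data.frame(zs)))
  structure(out, raw_features = feats, excluded = excluded,
            class = c("point_signatures", class(out)))
}

signature_matrix <- function(signatures) {
  as.matrix(signatures[, setdiff(names(signatures), c("point_id", "seed_label"))])
}

#' Group point signatures with a seeded K-nearest-neighbour rule
#'
#' Reproduces annotation-seeded clustering of dynamic signatures into two
#' groups: a seeded random split keeps `1 - holdout_fraction` of the
#' points as labelled references (labels from the ROI each point was
#' detected in), and every held-out point is assigned the majority label
#' among its `k` nearest references (Euclidean metric on the standardized
#' features). Vote ties are broken toward the class whose reference
#' centroid is nearer; neighbour handling is sort-stable so permuting
#' point order cannot change assignments. Reference points keep their
#' seed labels. An unsupervised 2-means mode (`method = "kmeans"`) is
#' available for comparison; its clusters are named by majority seed
#' label.
#'
#' @param signatures A [build_signatures()] tibble.
#' @param k Neighbour count (default 5).
#' @param holdout_fraction Fraction of points withheld from the reference
#'   set and re-assigned (default 0.5).
#' @param seed Seed for the reference/held-out partition.
#' @param method `"knn"` (default) or `"kmeans"`.
#' @return A `grouping_result`: `assignments` tibble (`point_id`,
#'   `seed_label`, `assigned`, `held_out`), `agreement_with_seed`
#'   (fraction of held-out assignments matching their seed label), and
#'   the parameters used. Supports [tidy()] and [glance()].
#' @export
knn_group <- function(signatures, k = 5, holdout_fraction = 0.5, seed = 17,
                      method = c("knn", "kmeans")) {
  method <- match.arg(method)
  X <- signature_matrix(signatures)
  lab <- signatures$seed_label
  n <- nrow(X)
  ord <- order(signatures$point_id)  # sort-stable under input permutation
  if (method == "kmeans") {
    km <- with_seed(seed, stats::kmeans(X[ord, , drop = FALSE], centers = 2,
                                        nstart = 10))
    cl <- integer(n); cl[ord] <- km$cluster
    # name clusters by majority seed label
    name_of <- vapply(1:2, function(c) {
      names(sort(table(lab[cl == c]), decreasing = TRUE))[1]
    }, character(1))
    if (name_of[1] == name_of[2]) name_of[2] <- setdiff(unique(lab), name_of[1])[1] %||% name_of[2]
    assigned <- name_of[cl]
    held <- rep(TRUE, n)
  } else {
    classes <- sort(unique(lab))
    if (length(classes) != 2) {
      abort("knn grouping expects exactly two seed classes",
            class = "fluotrack_validation_error")
    }
    ref_idx <- with_seed(seed, {
      unlist(lapply(classes, function(cl2) {
        i <- ord[lab[ord] == cl2]
        n_ref <- max(1L, round(length(i) * (1 - holdout_fraction)))
        sort(i[sample.int(length(i), n_ref)])
      }))
    })
    held <- !(seq_len(n) %in% ref_idx)
    per_class <- table(lab[ref_idx])
    if (any(per_class < k)) {
      abort(sprintf("a class has fewer than k = %d reference points (%s); use a smaller k",
                    k, paste(sprintf("%s: %d", names(per_class), per_class),
                             collapse = ", ")),
            class = "fluotrack_validation_error")
    }
    centroids <- lapply(classes, function(cl2) {
      colMeans(X[ref_idx[lab[ref_idx] == cl2], , drop = FALSE])
    })
    names(centroids) <- classes
    assigned <- lab
    ref_ord <- ref_idx[order(signatures$point_id[ref_idx])]
    for (i in which(held)) {
      d2 <- colSums((t(X[ref_ord, , drop = FALSE]) - X[i, ])^2)
      nn <- ref_ord[order(d2)[seq_len(k)]]
      votes <- table(factor(lab[nn], levels = classes))
      if (votes[1] != votes[2]) {
        assigned[i] <- classes[which.max(votes)]
      } else {
        dc <- vapply(classes, function(cl2) sum((X[i, ] - centroids[[cl2]])^2),
                     numeric(1))
        assigned[i] <- classes[which.min(dc)]
      }
    }
  }
  res <- tibble::tibble(point_id = signatures$point_id, seed_label = lab,
                        assigned = assigned, held_out = held)
  agree <- if (any(held)) mean(res$assigned[held] == res$seed_label[held]) else NA_real_
  structure(list(assignments = res, agreement_with_seed = agree,
                 k = k, holdout_fraction = holdout_fraction, seed = seed,
                 method = method),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat(sprintf("<grouping_result> %s: %d points, agreement with seed labels %.1f%%\n",
              x$method, nrow(x$assignments), 100 * x$agreement_with_seed))
  invisible(x)
}

#' @describeIn knn_group Assignments as a tidy tibble.
#' @param x A `grouping_result`.
#' @param ... Unused.
#' @export
tidy.grouping_result <- function(x, ...) x$assignments

#' @describeIn knn_group One-row summary.
#' @export
glance.grouping_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_points = nrow(x$assignments),
                 n_held_out = sum(x$assignments$held_out),
                 agreement_with_seed = x$agreement_with_seed, k = x$k)
}

#' Compare automatic and manual groupings
#'
#' Pairs each point's cluster-mean intensity under the automatic grouping
#' with the same quantity under the manual (seed) grouping and applies the
#' two-sided Wilcoxon signed-rank test: identical groupings give all-zero
#' differences and p = 1 (flagged).
#'
#' @param auto A `grouping_result`.
#' @param manual_labels Named character vector or tibble
#'   (`point_id`, `label`) of the manual grouping.
#' @param point_means Named numeric vector of per-point time-averaged
#'   intensities (g.u.).
#' @return Tibble with `statistic`, `p_value`, `all_zero` (TRUE when every
#'   pairwise difference is zero).
#' @export
compare_groupings <- function(auto, manual_labels, point_means) {
  a <- auto$assignments
  if (is.data.frame(manual_labels)) {
    manual <- setNames(manual_labels$label, manual_labels$point_id)
  } else {
    manual <- manual_labels
  }
  manual <- manual[a$point_id]
  pm <- point_means[a$point_id]
  group_mean <- function(groups) {
    means <- tapply(pm, groups, mean)
    unname(means[groups])
  }
  v_auto <- group_mean(a$assigned)
  v_manual <- group_mean(manual)
  wilcoxon_signed_rank(v_auto, v_manual)
}
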