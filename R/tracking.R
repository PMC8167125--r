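#' Tracker configuration
#'
#' Tunable parameters of the feature detection / KLT tracking stage.
#'
#' @param quality_level Fraction of the maximum minimum-eigenvalue corner
#'   response below which candidate corners are discarded.
#' @param max_points Maximum feature points per ROI.
#' @param min_distance Minimum pairwise distance between accepted corners
#'   (pixels).
#' @param win KLT integration window side (odd, pixels).
#' @param levels Pyramid levels for the coarse-to-fine KLT solve.
#' @param fb_max_px Forward-backward re-track error above which a point is
#'   invalidated.
#' @param min_points_alive Absolute floor of valid points below which
#'   tracking is declared lost.
#' @param min_alive_frac Fractional floor: tracking is lost when fewer than
#'   `min_alive_frac` of the initially detected points survive.
#' @param min_inlier_ratio Tracking is lost when the robust transform keeps
#'   fewer than this fraction of correspondences as inliers.
#' @param auto_reinit Re-detect features inside the last known polygon once
#'   the scene recovers (default off: clinical re-selection was manual, via
#'   additional annotations with later anchor frames and the same label).
#' @param transform `"similarity"` (rotation + isotropic scale +
#'   translation; endoscope motion at near-constant working distance) or
#'   `"translation"`.
#' @return A `track_config` list.
#' @export
track_config <- function(quality_level = 0.01, max_points = 50, min_distance = 7,
                         win = 21, levels = 3, fb_max_px = 1.5,
                         min_points_alive = 3, min_alive_frac = 0.25,
                         min_inlier_ratio = 0.5, auto_reinit = FALSE,
                         transform = c("similarity", "translation")) {
  structure(list(quality_level = quality_level, max_points = max_points,
                 min_distance = min_distance, win = win, levels = levels,
                 fb_max_px = fb_max_px, min_points_alive = min_points_alive,
                 min_alive_frac = min_alive_frac,
                 min_inlier_ratio = min_inlier_ratio,
                 auto_reinit = auto_reinit,
                 transform = match.arg(transform)),
            class = "track_config")
}

#' Detect corner features inside an ROI
#'
#' Minimum-eigenvalue (Shi-Tomasi) corner detection restricted to the
#' polygon interior. Candidates with response at least
#' `quality_level * max(response)` are ranked by response and accepted
#' greedily under the `min_distance` spacing constraint, up to `max_points`.
#' Deterministic: ties are broken by pixel position.
#'
#' @param frame White-light frame (`h x w x 3` array or grey matrix).
#' @param polygon ROI vertex matrix.
#' @param quality_level,max_points,min_distance See [track_config()].
#' @return Tibble with `point_id`, `x`, `y`, `response`, `valid`. A flat,
#'   featureless region yields zero rows with a warning, not an error.
#' @export
detect_features <- function(frame, polygon, quality_level = 0.01,
                            max_points = 50, min_distance = 7) {
  grey <- rgb_to_grey(frame)
  polygon <- as_polygon(polygon)
  resp <- cpp_min_eig_response(grey)
  mask <- polygon_mask(polygon, dim(grey))
  vals <- resp[mask]
  empty <- tibble::tibble(point_id = integer(), x = double(), y = double(),
                          response = double(), valid = logical())
  if (length(vals) == 0 || max(vals) <= 0) {
    warn("no detectable corners inside the ROI")
    return(empty)
  }
  thr <- quality_level * max(vals)
  idx <- which(mask & resp >= thr, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warn("no detectable corners inside the ROI")
    return(empty)
  }
  cand <- tibble::tibble(x = idx[, 2] - 1, y = idx[, 1] - 1,
                         response = resp[idx])
  cand <- cand[order(-cand$response, cand$y, cand$x), ]
  keep_x <- numeric(0); keep_y <- numeric(0); keep_r <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep_x) >= max_points) break
    if (length(keep_x) == 0 ||
        min((keep_x - cand$x[i])^2 + (keep_y - cand$y[i])^2) >= min_distance^2) {
      keep_x <- c(keep_x, cand$x[i])
      keep_y <- c(keep_y, cand$y[i])
      keep_r <- c(keep_r, cand$response[i])
    }
  }
  tibble::tibble(point_id = seq_along(keep_x), x = keep_x, y = keep_y,
                 response = keep_r, valid = TRUE)
}

#' Track feature points between two consecutive frames
#'
#' Pyramidal Kanade-Lucas-Tomasi sparse optical flow with a
#' forward-backward consistency check: each point is tracked
#' `prev -> next`, then re-tracked `next -> prev`; points whose return
#' position misses the start by more than `fb_max_px`, or for which the
#' tracker itself fails (singular gradient matrix, window out of frame),
#' are invalidated.
#'
#' @param prev_frame,next_frame Same-size white-light frames.
#' @param points Tibble with `point_id`, `x`, `y`, `valid` (as returned by
#'   [detect_features()] or a previous `track_step()`).
#' @param fb_max_px,win,levels See [track_config()].
#' @return `points` with updated positions, `valid` flags and an `fb_err`
#'   column.
#' @export
track_step <- function(prev_frame, next_frame, points, fb_max_px = 1.5,
                       win = 21, levels = 3) {
  pg <- rgb_to_grey(prev_frame); ng <- rgb_to_grey(next_frame)
  if (!all(dim(pg) == dim(ng))) {
    abort("frame size mismatch between consecutive frames",
          class = "fluotrack_validation_error")
  }
  if (nrow(points) == 0) {
    points$fb_err <- double()
    return(points)
  }
  pts <- cbind(points$x, points$y)
  fwd <- cpp_klt_track(pg, ng, pts, win = win, levels = levels)
  back <- cpp_klt_track(ng, pg, fwd[, 1:2, drop = FALSE], win = win,
                        levels = levels)
  fb_err <- sqrt((back[, 1] - pts[, 1])^2 + (back[, 2] - pts[, 2])^2)
  out <- points
  out$x <- fwd[, 1]
  out$y <- fwd[, 2]
  out$fb_err <- fb_err
  out$valid <- points$valid & fwd[, 3] > 0 & back[, 3] > 0 & fb_err <= fb_max_px
  out
}

#' Propagate ROI geometry through point correspondences
#'
#' Robustly fits a similarity transform (rotation + isotropic scale +
#' translation, IRLS with a median-residual cutoff so gross outliers are
#' rejected) to the valid correspondences and applies it to every polygon
#' vertex. Falls back to a median translation when fewer than 3 inliers
#' survive.
#'
#' @param polygon ROI vertex matrix at the previous frame.
#' @param correspondences Data frame with `x_from`, `y_from`, `x_to`,
#'   `y_to` (valid point positions in the previous and current frame).
#' @param min_points_alive Below this many correspondences a
#'   `fluotrack_tracking_lost` condition is raised (consumed by
#'   [run_tracking()]).
#' @param transform `"similarity"` or `"translation"`.
#' @return The propagated polygon, with attributes `params` (a, b, tx, ty),
#'   `inlier_ratio` and `translation_only`.
#' @export
propagate_roi <- function(polygon, correspondences, min_points_alive = 3,
                          transform = c("similarity", "translation")) {
  transform <- match.arg(transform)
  polygon <- as_polygon(polygon)
  n <- nrow(correspondences)
  if (n < min_points_alive) {
    abort(sprintf("only %d valid correspondences (< %d): tracking lost",
                  n, min_points_alive),
          class = "fluotrack_tracking_lost")
  }
  from <- cbind(correspondences$x_from, correspondences$y_from)
  to <- cbind(correspondences$x_to, correspondences$y_to)
  if (transform == "translation") {
    d <- to - from
    fit <- list(params = c(a = 1, b = 0, tx = median(d[, 1]), ty = median(d[, 2])),
                inliers = rep(TRUE, n), inlier_ratio = 1,
                translation_only = TRUE)
  } else {
    fit <- fit_similarity_robust(from, to)
  }
  out <- apply_similarity(fit$params, polygon)
  structure(out, params = fit$params, inlier_ratio = fit$inlier_ratio,
            translation_only = fit$translation_only)
}

new_track_result <- function(roi_label, tissue_class, anchor_frame, polygons,
                             point_tracks, gaps, reinit_frames, fps, n_frames) {
  censored_s <- if (nrow(gaps)) sum(gaps$end_frame - gaps$start_frame + 1) / fps else 0
  structure(list(roi_label = roi_label, tissue_class = tissue_class,
                 anchor_frame = anchor_frame, polygons = polygons,
                 point_tracks = point_tracks, gaps = gaps,
                 reinit_frames = reinit_frames, fps = fps,
                 n_frames = n_frames, censored_s = censored_s),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  cat(sprintf("<track_result> ROI '%s' (%s): frames %d-%d, %d gap(s), %.2f s censored\n",
              x$roi_label, x$tissue_class, x$anchor_frame, x$n_frames - 1,
              nrow(x$gaps), x$censored_s))
  invisible(x)
}

#' @describeIn run_tracking Per-frame tidy summary of one track result:
#'   frame, time, tracked flag, polygon centroid and area.
#' @param x A `track_result`.
#' @param ... Unused.
#' @export
tidy.track_result <- function(x, ...) {
  purrr::map_dfr(seq(x$anchor_frame, x$n_frames - 1), function(k) {
    poly <- x$polygons[[k + 1]]
    if (is.null(poly)) {
      tibble::tibble(roi_label = x$roi_label, frame = k, time_s = k / x$fps,
                     tracked = FALSE, centroid_x = NA_real_,
                     centroid_y = NA_real_, area_px = NA_real_)
    } else {
      cen <- polygon_centroid(poly)
      tibble::tibble(roi_label = x$roi_label, frame = k, time_s = k / x$fps,
                     tracked = TRUE, centroid_x = cen[1], centroid_y = cen[2],
                     area_px = abs(polygon_area(poly)))
    }
  })
}

#' @describeIn run_tracking One-row summary: frames tracked, gap count,
#'   censored seconds, re-initializations.
#' @export
glance.track_result <- function(x, ...) {
  tracked <- sum(!purrr::map_lgl(x$polygons, is.null))
  tibble::tibble(roi_label = x$roi_label, tissue_class = x$tissue_class,
                 n_frames = x$n_frames, frames_tracked = tracked,
                 n_gaps = nrow(x$gaps), censored_s = x$censored_s,
                 n_reinits = length(x$reinit_frames))
}

#' Track annotated ROIs through a recording
#'
#' For each labelled ROI: corner features are detected at the anchor frame,
#' tracked forward with pyramidal KLT, and the polygon is propagated by a
#' robust similarity fit each frame. Tracking is declared lost when too few
#' points survive or the transform inlier ratio collapses; a gap then opens
#' and is closed either by a later manual annotation with the same label or
#' (with `auto_reinit = TRUE`) by re-detecting features inside the last
#' known polygon once the scene supports it. Gaps are collated and the
#' censored seconds totalled. The procedure is deterministic: identical
#' inputs and configuration give identical results.
#'
#' @param stream A `frame_stream` (see [load_stream()]).
#' @param annotations Annotation tibble; several rows may share a label, in
#'   which case rows after the first (by anchor frame) act as manual
#'   re-selections consumed when tracking has been lost.
#' @param config A [track_config()].
#' @return Named list of `track_result` objects, one per ROI label.
#' @export
run_tracking <- function(stream, annotations, config = track_config()) {
  stopifnot(inherits(stream, "frame_stream"))
  validate_annotations(annotations, frame_dim = c(stream$height, stream$width))
  if (any(annotations$anchor_frame >= stream$n_frames | annotations$anchor_frame < 0)) {
    abort("annotation anchor_frame beyond stream end",
          class = "fluotrack_validation_error")
  }
  n <- stream$n_frames
  labels <- unique(annotations$label)

  states <- lapply(labels, function(lb) {
    rows <- annotations[annotations$label == lb, ]
    rows <- rows[order(rows$anchor_frame), ]
    list(label = lb, tissue_class = rows$tissue_class[1],
         anchors = rows, anchor0 = rows$anchor_frame[1],
         mode = "waiting", polygon = NULL, last_polygon = NULL,
         points = NULL, initial_count = 0L, id_offset = 0L,
         gap_start = NA_integer_, gap_reason = NA_character_,
         polygons = vector("list", n), gaps = list(),
         reinits = integer(0), track_rows = vector("list", n))
  })
  names(states) <- labels

  detect_in <- function(grey, polygon) {
    withCallingHandlers(
      detect_features(grey, polygon, config$quality_level, config$max_points,
                      config$min_distance),
      warning = function(w) invokeRestart("muffleWarning"))
  }

  start_tracking <- function(s, grey, polygon, k, is_reinit) {
    pts <- detect_in(grey, polygon)
    need <- max(config$min_points_alive,
                ceiling(config$min_alive_frac * max(s$initial_count, 1L)))
    if (nrow(pts) >= max(config$min_points_alive,
                         if (is_reinit) need else 0)) {
      pts$point_id <- pts$point_id + s$id_offset
      s$id_offset <- s$id_offset + nrow(pts)
      s$points <- pts
      s$initial_count <- nrow(pts)
      s$polygon <- as_polygon(polygon)
      s$last_polygon <- s$polygon
      s$mode <- "tracking"
      s$polygons[[k + 1]] <- s$polygon
      if (is_reinit) {
        if (k - 1 >= s$gap_start) {
          s$gaps[[length(s$gaps) + 1]] <-
            list(s$gap_start, k - 1, s$gap_reason)
        }
        s$reinits <- c(s$reinits, k)
        s$gap_start <- NA_integer_
      }
      s$track_rows[[k + 1]] <- cbind(s$points$point_id, s$points$x, s$points$y, 1)
    } else if (!is_reinit) {
      s$mode <- "gap"
      s$gap_start <- k
      s$gap_reason <- "no_features"
      s$last_polygon <- as_polygon(polygon)
    }
    s
  }

  close_open_gap <- function(s, n) {
    if (s$mode == "gap") {
      s$gaps[[length(s$gaps) + 1]] <- list(s$gap_start, n - 1, s$gap_reason)
    }
    s
  }

  prev_grey <- NULL
  for (k in seq(0L, n - 1L)) {
    grey <- rgb_to_grey(get_frame(stream, k)$rgb)
    for (lb in labels) {
      s <- states[[lb]]
      manual <- s$anchors[s$anchors$anchor_frame == k, ]
      if (s$mode == "waiting") {
        if (k == s$anchor0) {
          s <- start_tracking(s, grey, s$anchors$polygon[[1]], k, is_reinit = FALSE)
        }
      } else if (s$mode == "tracking") {
        live <- s$points$valid
        stepped <- s$points
        stepped$fb_err <- NA_real_
        stepped[live, ] <- track_step(prev_grey, grey, s$points[live, ],
                                      fb_max_px = config$fb_max_px,
                                      win = config$win, levels = config$levels)
        alive <- which(stepped$valid)
        need <- max(config$min_points_alive,
                    ceiling(config$min_alive_frac * s$initial_count))
        lost <- FALSE; reason <- NA_character_
        if (length(alive) < need) {
          lost <- TRUE; reason <- "points_lost"
        } else {
          corr <- data.frame(x_from = s$points$x[alive],
                             y_from = s$points$y[alive],
                             x_to = stepped$x[alive], y_to = stepped$y[alive])
          newpoly <- tryCatch(
            propagate_roi(s$polygon, corr, config$min_points_alive,
                          config$transform),
            fluotrack_tracking_lost = function(e) NULL)
          if (is.null(newpoly) ||
              attr(newpoly, "inlier_ratio") < config$min_inlier_ratio) {
            lost <- TRUE; reason <- "low_inlier_ratio"
          }
        }
        if (lost) {
          s$mode <- "gap"
          s$gap_start <- k
          s$gap_reason <- reason
          s$last_polygon <- s$polygon
        } else {
          s$points <- stepped[, c("point_id", "x", "y", "response", "valid")]
          s$polygon <- as_polygon(newpoly)
          s$polygons[[k + 1]] <- s$polygon
          s$track_rows[[k + 1]] <- cbind(stepped$point_id, stepped$x,
                                         stepped$y, as.numeric(stepped$valid))
        }
      }
      if (s$mode == "gap") {
        if (nrow(manual) > 0 && k > s$anchor0) {
          s <- start_tracking(s, grey, manual$polygon[[1]], k, is_reinit = TRUE)
        } else if (config$auto_reinit && k > s$gap_start) {
          s <- start_tracking(s, grey, s$last_polygon, k, is_reinit = TRUE)
        }
      }
      states[[lb]] <- s
    }
    prev_grey <- grey
  }

  purrr::map(states, function(s) {
    s <- close_open_gap(s, n)
    gaps <- if (length(s$gaps)) {
      tibble::tibble(
        start_frame = purrr::map_int(s$gaps, ~ as.integer(.x[[1]])),
        end_frame = purrr::map_int(s$gaps, ~ as.integer(.x[[2]])),
        reason = purrr::map_chr(s$gaps, ~ .x[[3]] %||% "tracking_lost"))
    } else {
      tibble::tibble(start_frame = integer(), end_frame = integer(),
                     reason = character())
    }
    rows <- do.call(rbind, Filter(Negate(is.null), s$track_rows))
    pt <- if (is.null(rows)) {
      tibble::tibble(point_id = integer(), frame = integer(), x = double(),
                     y = double(), valid = logical())
    } else {
      frames <- rep(which(!purrr::map_lgl(s$track_rows, is.null)) - 1L,
                    purrr::map_int(Filter(Negate(is.null), s$track_rows), nrow))
      tibble::tibble(point_id = as.integer(rows[, 1]), frame = frames,
                     x = rows[, 2], y = rows[, 3], valid = rows[, 4] > 0)
    }
    new_track_result(s$label, s$tissue_class, s$anchor0, s$polygons, pt,
                     gaps, s$reinits, stream$fps, n)
  })
}
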