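#' Extract an NIR intensity trace from tracked geometry
#'
#' For every non-gap frame from the ROI anchor onward, the mean NIR grey
#' value over the pixels enclosed by the propagated polygon (pixel-center
#' even-odd rule) becomes one sample; frames inside tracking gaps emit
#' gap-flagged samples with no intensity. A polygon degenerating to zero
#' enclosed pixels also yields a gap sample, with a warning.
#'
#' @param stream The `frame_stream` the tracking ran on.
#' @param track_result A `track_result` from [run_tracking()].
#' @param downsample_fps Optional lower sampling rate (e.g. 1 fps to
#'   reproduce manual frame-by-frame measurement).
#' @return An [intensity_trace()] carrying the ROI label and tissue class.
#' @export
extract_trace <- function(stream, track_result, downsample_fps = NULL) {
  stopifnot(inherits(stream, "frame_stream"), inherits(track_result, "track_result"))
  if (track_result$n_frames != stream$n_frames) {
    abort("track result does not cover the stream",
          class = "fluotrack_validation_error")
  }
  ks <- seq(track_result$anchor_frame, stream$n_frames - 1)
  m <- length(ks)
  tvec <- numeric(m); ivec <- rep(NA_real_, m)
  npix <- integer(m); gap <- logical(m)
  warned <- FALSE
  for (j in seq_along(ks)) {
    k <- ks[j]
    tvec[j] <- k / stream$fps
    poly <- track_result$polygons[[k + 1]]
    if (is.null(poly)) {
      gap[j] <- TRUE
    } else {
      nir <- get_frame(stream, k)$nir
      mv <- cpp_polygon_mean(nir, poly[, 1], poly[, 2])
      if (mv[2] == 0) {
        gap[j] <- TRUE
        if (!warned) {
          warn(sprintf("ROI '%s' encloses zero pixel centers at frame %d",
                       track_result$roi_label, k))
          warned <- TRUE
        }
      } else {
        ivec[j] <- min(max(mv[1], 0), 255)
        npix[j] <- as.integer(mv[2])
      }
    }
  }
  tr <- intensity_trace(tvec, ivec, npix, gap,
                        roi_label = track_result$roi_label,
                        tissue_class = track_result$tissue_class,
                        fps_effective = stream$fps)
  if (!is.null(downsample_fps)) tr <- downsample_trace(tr, downsample_fps)
  tr
}

#' Spot mean fluorescence in a square box
#'
#' Arithmetic mean of the grey values in a `side_px x side_px` box centered
#' on `center` (for even sides the box is biased one pixel toward the
#' top-left). The conventional clinical spot size is 25 x 25 pixels. The
#' box must lie fully inside the image; partial boxes are an error rather
#' than silently clipped.
#'
#' @param nir_image Grey matrix, values 0-255.
#' @param center `c(x, y)` 0-based pixel coordinates of the box center.
#' @param side_px Box side in pixels (default 25).
#' @param label Optional `"tumour"` / `"control"` tag.
#' @return One-row tibble: `center_x`, `center_y`, `side_px`,
#'   `mean_intensity_gu`, `label`.
#' @export
spot_mean <- function(nir_image, center, side_px = 25, label = NA_character_) {
  if (side_px < 1) {
    abort("side_px must be >= 1", class = "fluotrack_validation_error")
  }
  h <- nrow(nir_image); w <- ncol(nir_image)
  cx <- round(center[1]); cy <- round(center[2])
  half_lo <- floor((side_px - 1) / 2)   # even sides bias toward top-left
  half_hi <- side_px - 1 - half_lo
  x0 <- cx - half_lo; x1 <- cx + half_hi
  y0 <- cy - half_lo; y1 <- cy + half_hi
  if (x0 < 0 || y0 < 0 || x1 > w - 1 || y1 > h - 1) {
    abort(sprintf("%d x %d box at (%g, %g) extends outside the %d x %d image",
                  side_px, side_px, center[1], center[2], h, w),
          class = "fluotrack_validation_error")
  }
  vals <- nir_image[(y0:y1) + 1, (x0:x1) + 1]
  tibble::tibble(center_x = cx, center_y = cy, side_px = as.integer(side_px),
                 mean_intensity_gu = mean(vals), label = label)
}

#' Assess photobleaching on a static-specimen trace
#'
#' Percent signal decline between the start and end of a continuous
#' recording of a motionless specimen:
#' `100 * (mean over first window - mean over last window) / mean over
#' first window`, with window means taken over `window_s` seconds at each
#' end of `[t_start, t_end]`.
#'
#' @param trace An intensity trace (gap samples are ignored).
#' @param t_start,t_end Analysis interval (defaults to the whole trace).
#' @param window_s Window length in seconds (default 30).
#' @return Percent decline (positive = signal loss).
#' @export
photobleach_assess <- function(trace, t_start = NULL, t_end = NULL,
                               window_s = 30) {
  ok <- !trace$gap_flag & !is.na(trace$intensity_gu)
  t <- trace$time_s[ok]; v <- trace$intensity_gu[ok]
  if (length(t) == 0) abort("empty trace", class = "fluotrack_validation_error")
  t_start <- t_start %||% min(t)
  t_end <- t_end %||% max(t)
  if (t_start >= t_end) {
    abort("t_start must precede t_end", class = "fluotrack_validation_error")
  }
  first <- v[t >= t_start & t <= t_start + window_s]
  last <- v[t >= t_end - window_s & t <= t_end]
  if (length(first) == 0 || length(last) == 0) {
    abort("window contains no samples", class = "fluotrack_validation_error")
  }
  m1 <- mean(first)
  if (m1 == 0) {
    abort("first-window mean intensity is zero: percent decline undefined",
          class = "fluotrack_validation_error")
  }
  100 * (m1 - mean(last)) / m1
}
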