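#' Intensity traces
#'
#' An intensity trace is a tibble of NIR fluorescence samples for one ROI:
#' `time_s` (strictly increasing), `intensity_gu` (mean grey value 0-255,
#' `NA` on gap samples), `n_pixels` (pixels averaged, 0 on gaps) and
#' `gap_flag` (TRUE where tracking was interrupted). Metadata ride along as
#' attributes: `roi_label`, `tissue_class`, `fps_effective`.
#'
#' @param time_s Numeric vector of sample times (seconds, strictly
#'   increasing).
#' @param intensity_gu Mean grey intensities (0-255; `NA` where `gap_flag`).
#' @param n_pixels Integer pixel counts per sample.
#' @param gap_flag Logical gap indicator.
#' @param roi_label,tissue_class,fps_effective Trace metadata.
#' @return An `intensity_trace` tibble.
#' @export
intensity_trace <- function(time_s, intensity_gu,
                            n_pixels = rep(1L, length(time_s)),
                            gap_flag = rep(FALSE, length(time_s)),
                            roi_label = NA_character_,
                            tissue_class = NA_character_,
                            fps_effective = NULL) {
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    abort("trace times must be strictly increasing",
          class = "fluotrack_format_error")
  }
  ok <- !gap_flag & !is.na(intensity_gu)
  if (any(intensity_gu[ok] < 0 | intensity_gu[ok] > 255)) {
    abort("intensity values must lie in [0, 255]",
          class = "fluotrack_validation_error")
  }
  if (is.null(fps_effective)) {
    fps_effective <- if (length(time_s) > 1) 1 / median(diff(time_s)) else NA_real_
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        intensity_gu = as.numeric(intensity_gu),
                        n_pixels = as.integer(n_pixels),
                        gap_flag = as.logical(gap_flag))
  structure(out,
            roi_label = roi_label, tissue_class = tissue_class,
            fps_effective = fps_effective,
            class = c("intensity_trace", class(out)))
}

trace_meta <- function(trace) {
  list(roi_label = attr(trace, "roi_label") %||% NA_character_,
       tissue_class = attr(trace, "tissue_class") %||% NA_character_,
       fps_effective = attr(trace, "fps_effective") %||%
         (if (nrow(trace) > 1) 1 / median(diff(trace$time_s)) else NA_real_))
}

#' Read and write intensity-trace CSV files
#'
#' Comma-separated with dot decimals and the exact header
#' `time_s,intensity_gu,n_pixels,gap_flag`; `gap_flag` is written as 0/1.
#' Writing then reading is the identity to at least 6 decimal places. An
#' empty trace writes a header-only file.
#'
#' @param trace An [intensity_trace()] tibble.
#' @param path CSV file path.
#' @return `read_trace()` returns the trace tibble.
#' @export
write_trace <- function(trace, path) {
  df <- tibble::tibble(time_s = trace$time_s,
                       intensity_gu = trace$intensity_gu,
                       n_pixels = trace$n_pixels,
                       gap_flag = as.integer(trace$gap_flag))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("trace file not found: '%s'", path),
          class = "fluotrack_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          time_s = readr::col_double(),
                          intensity_gu = readr::col_double(),
                          n_pixels = readr::col_integer(),
                          gap_flag = readr::col_integer()))
  if (!identical(names(df), c("time_s", "intensity_gu", "n_pixels", "gap_flag"))) {
    abort(sprintf("'%s' is not a trace CSV (unexpected header)", path),
          class = "fluotrack_format_error")
  }
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0)) {
    abort(sprintf("non-monotone time column in '%s'", path),
          class = "fluotrack_format_error")
  }
  intensity_trace(df$time_s, df$intensity_gu, df$n_pixels,
                  as.logical(df$gap_flag))
}

#' Decimate a trace to a lower sampling rate
#'
#' Keeps every `round(fps / target_fps)`-th sample starting from the first,
#' reproducing low-rate manual sampling (e.g. 30 fps down to 1 fps).
#'
#' @param trace An intensity trace.
#' @param target_fps Target sampling rate (must not exceed the trace rate).
#' @return The decimated `intensity_trace`.
#' @export
downsample_trace <- function(trace, target_fps) {
  meta <- trace_meta(trace)
  fps <- meta$fps_effective
  if (target_fps > fps + 1e-9) {
    abort("target_fps exceeds the trace sampling rate",
          class = "fluotrack_validation_error")
  }
  stride <- max(1L, as.integer(round(fps / target_fps)))
  idx <- seq(1L, nrow(trace), by = stride)
  intensity_trace(trace$time_s[idx], trace$intensity_gu[idx],
                  trace$n_pixels[idx], trace$gap_flag[idx],
                  roi_label = meta$roi_label, tissue_class = meta$tissue_class,
                  fps_effective = fps / stride)
}
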