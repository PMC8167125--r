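#' Stream configuration for dual-channel recordings
#'
#' Describes where the white-light (RGB) and near-infrared (NIR) channels
#' live and how to decode them into synchronized frame pairs. Supported
#' sources are numbered PNG/TIFF image-sequence directories and in-memory
#' lists of frame arrays; dual-display recorders commonly store both
#' channels side by side in a single frame, which `layout` describes.
#'
#' @param source A directory of numbered PNG/TIFF frames, a list of frame
#'   arrays (`height x width x 3` or `height x width`, grey values 0-255),
#'   or for `layout = "two_files"` a list of two such sources (RGB first,
#'   NIR second).
#' @param layout One of `"side_by_side_lr"` (RGB left, NIR right),
#'   `"side_by_side_rl"`, `"two_files"`, `"single_nir"`.
#' @param fps Acquisition frame rate in frames/second (must be positive).
#' @param nir_conversion How to collapse a color-stored NIR channel to grey:
#'   `"luma"` (ITU-R BT.601 weights, the default because NIR overlays are
#'   often stored in color), `"green_channel"`, or `"max_channel"`.
#' @param downsample_fps Optional target rate; frames are decimated to the
#'   nearest integer stride (e.g. 30 fps down to 1 fps keeps every 30th
#'   frame), reproducing low-rate manual sampling regimes.
#' @return A `stream_config` list.
#' @export
stream_config <- function(source, layout = c("side_by_side_lr", "side_by_side_rl",
                                             "two_files", "single_nir"),
                          fps, nir_conversion = c("luma", "green_channel", "max_channel"),
                          downsample_fps = NULL) {
  layout <- match.arg(layout)
  nir_conversion <- match.arg(nir_conversion)
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0) {
    abort("fps must be a positive number", class = "fluotrack_validation_error")
  }
  if (!is.null(downsample_fps) && (downsample_fps <= 0 || downsample_fps > fps)) {
    abort("downsample_fps must lie in (0, fps]", class = "fluotrack_validation_error")
  }
  structure(list(source = source, layout = layout, fps = fps,
                 nir_conversion = nir_conversion, downsample_fps = downsample_fps),
            class = "stream_config")
}

#' Convert a color frame to a grey NIR channel
#'
#' @param img `height x width x 3` array or `height x width` matrix, 0-255.
#' @param method `"luma"`, `"green_channel"` or `"max_channel"`.
#' @return `height x width` matrix of grey values.
#' @export
nir_convert <- function(img, method = c("luma", "green_channel", "max_channel")) {
  method <- match.arg(method)
  if (length(dim(img)) == 2) return(img)
  switch(method,
    luma = 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3],
    green_channel = img[, , 2],
    max_channel = pmax(img[, , 1], img[, , 2], img[, , 3])
  )
}

#' Split or re-join a side-by-side dual-display frame
#'
#' `split_side_by_side()` halves a frame at `width / 2` into its white-light
#' and NIR panes; `join_side_by_side()` is its exact inverse.
#'
#' @param img Frame array, `height x width x channels` (width even).
#' @param layout `"side_by_side_lr"` (RGB left) or `"side_by_side_rl"`.
#' @return For the split, `list(rgb = , nir_raw = )`; for the join, the
#'   reassembled frame.
#' @export
split_side_by_side <- function(img, layout = c("side_by_side_lr", "side_by_side_rl")) {
  layout <- match.arg(layout)
  w <- dim(img)[2]
  if (w %% 2 != 0) {
    abort(sprintf("side-by-side frame width must be even, got %d", w),
          class = "fluotrack_layout_error")
  }
  half <- w / 2
  left <- if (length(dim(img)) == 3) img[, seq_len(half), , drop = FALSE] else img[, seq_len(half), drop = FALSE]
  right <- if (length(dim(img)) == 3) img[, half + seq_len(half), , drop = FALSE] else img[, half + seq_len(half), drop = FALSE]
  if (layout == "side_by_side_lr") list(rgb = left, nir_raw = right)
  else list(rgb = right, nir_raw = left)
}

#' @rdname split_side_by_side
#' @param rgb,nir_raw The two panes returned by `split_side_by_side()`.
#' @export
join_side_by_side <- function(rgb, nir_raw, layout = c("side_by_side_lr", "side_by_side_rl")) {
  layout <- match.arg(layout)
  bind <- function(a, b) {
    if (length(dim(a)) == 3) {
      out <- array(0, dim = c(dim(a)[1], dim(a)[2] + dim(b)[2], dim(a)[3]))
      out[, seq_len(dim(a)[2]), ] <- a
      out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
      out
    } else {
      cbind(a, b)
    }
  }
  if (layout == "side_by_side_lr") bind(rgb, nir_raw) else bind(nir_raw, rgb)
}

read_image_file <- function(path) {
  img <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE)) abort("package 'png' required")
      png::readPNG(path)
    } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE)) abort("package 'tiff' required")
      tiff::readTIFF(path)
    } else {
      abort(sprintf("unsupported image format: %s", path))
    }
  }, error = function(e) {
    abort(sprintf("cannot read frame file '%s': %s", path, conditionMessage(e)),
          class = "fluotrack_io_error")
  })
  if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]  # drop alpha
  img * 255
}

# Normalize one source argument to list(n = frame count, get = function(k0) array).
frame_source <- function(source) {
  if (is.character(source) && length(source) == 1) {
    if (!dir.exists(source)) {
      abort(sprintf("frame directory not found: '%s'", source),
            class = "fluotrack_io_error")
    }
    files <- sort(list.files(source, pattern = "\\.(png|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) {
      abort(sprintf("no PNG/TIFF frames in '%s'", source),
            class = "fluotrack_io_error")
    }
    list(n = length(files), get = function(k) read_image_file(files[k + 1]))
  } else if (is.list(source) && !is.null(dim(source[[1]]))) {
    list(n = length(source), get = function(k) source[[k + 1]])
  } else {
    abort("source must be a frame directory or a list of frame arrays",
          class = "fluotrack_validation_error")
  }
}

new_frame_stream <- function(n_frames, fps, get_pair, height, width) {
  structure(list(n_frames = n_frames, fps = fps, height = height,
                 width = width, get_pair = get_pair),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d frames, %g fps, %d x %d px (%.1f s)\n",
              x$n_frames, x$fps, x$width, x$height, x$n_frames / x$fps))
  invisible(x)
}

#' Load a dual-channel recording as a synchronized frame-pair stream
#'
#' Decodes the configured source(s) into an indexable stream of synchronized
#' white-light + NIR frame pairs. Frames are decoded lazily through
#' [get_frame()]; frame `k` carries timestamp `k / fps` with the first
#' analyzed frame at t = 0 s.
#'
#' @param config A [stream_config()].
#' @return A `frame_stream` object with fields `n_frames`, `fps`, `height`,
#'   `width`; access frames with [get_frame()].
#' @export
load_stream <- function(config) {
  stopifnot(inherits(config, "stream_config"))
  layout <- config$layout
  conv <- config$nir_conversion
  if (layout == "two_files") {
    if (!is.list(config$source) || length(config$source) != 2) {
      abort("layout 'two_files' requires a list of two sources",
            class = "fluotrack_validation_error")
    }
    src_rgb <- frame_source(config$source[[1]])
    src_nir <- frame_source(config$source[[2]])
    if (src_rgb$n != src_nir$n) {
      abort(sprintf("two_files sources differ in frame count (%d vs %d)",
                    src_rgb$n, src_nir$n),
            class = "fluotrack_sync_error")
    }
    n <- src_rgb$n
    make_pair <- function(k) {
      rgb <- src_rgb$get(k)
      if (length(dim(rgb)) == 2) rgb <- array(rgb, dim = c(dim(rgb), 3))
      list(rgb = rgb, nir = nir_convert(src_nir$get(k), conv))
    }
  } else {
    src <- frame_source(config$source)
    n <- src$n
    make_pair <- function(k) {
      img <- src$get(k)
      if (layout == "single_nir") {
        nir <- nir_convert(img, conv)
        rgb <- array(nir, dim = c(dim(nir), 3))
        list(rgb = rgb, nir = nir)
      } else {
        halves <- split_side_by_side(img, layout)
        rgb <- halves$rgb
        if (length(dim(rgb)) == 2) rgb <- array(rgb, dim = c(dim(rgb), 3))
        list(rgb = rgb, nir = nir_convert(halves$nir_raw, conv))
      }
    }
  }
  fps <- config$fps
  stride <- 1L
  if (!is.null(config$downsample_fps)) {
    stride <- max(1L, as.integer(round(fps / config$downsample_fps)))
  }
  eff_fps <- fps / stride
  n_eff <- length(seq(0L, n - 1L, by = stride))
  first <- make_pair(0L)
  h <- dim(first$rgb)[1]; w <- dim(first$rgb)[2]
  get_pair <- function(k) {
    p <- make_pair(k * stride)
    list(index = k, time_s = k / eff_fps, rgb = p$rgb, nir = p$nir)
  }
  new_frame_stream(n_eff, eff_fps, get_pair, h, w)
}

#' Fetch one synchronized frame pair from a stream
#'
#' @param stream A `frame_stream`.
#' @param index 0-based frame index.
#' @return List with `index`, `time_s`, `rgb` (`h x w x 3`), `nir` (`h x w`),
#'   grey values 0-255.
#' @export
get_frame <- function(stream, index) {
  stopifnot(inherits(stream, "frame_stream"))
  if (index < 0 || index >= stream$n_frames) {
    abort(sprintf("frame index %d outside stream [0, %d]", index,
                  stream$n_frames - 1),
          class = "fluotrack_validation_error")
  }
  stream$get_pair(as.integer(index))
}

#' Build a stream directly from in-memory frame pairs
#'
#' Used by the synthetic generator and for programmatic pipelines; frames
#' may be supplied as materialized lists or as generator functions of the
#' 0-based frame index (lazy, constant-memory).
#'
#' @param rgb List of `h x w x 3` arrays, or `function(k)` returning one.
#' @param nir List of `h x w` matrices, or `function(k)` returning one.
#' @param fps Frames per second.
#' @param n_frames Required when `rgb` is a function.
#' @return A `frame_stream`.
#' @export
stream_from_frames <- function(rgb, nir, fps, n_frames = NULL) {
  if (is.function(rgb)) {
    stopifnot(is.function(nir), !is.null(n_frames))
    first <- rgb(0L)
    get_pair <- function(k) list(index = k, time_s = k / fps,
                                 rgb = rgb(k), nir = nir(k))
    new_frame_stream(as.integer(n_frames), fps, get_pair,
                     dim(first)[1], dim(first)[2])
  } else {
    stopifnot(length(rgb) == length(nir), length(rgb) > 0)
    get_pair <- function(k) list(index = k, time_s = k / fps,
                                 rgb = rgb[[k + 1]], nir = nir[[k + 1]])
    new_frame_stream(length(rgb), fps, get_pair,
                     dim(rgb[[1]])[1], dim(rgb[[1]])[2])
  }
}

# Luma grey of a white-light frame, used by the tracker.
rgb_to_grey <- function(rgb) {
  if (length(dim(rgb)) == 2) rgb
  else 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}
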