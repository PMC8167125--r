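#' Region-of-interest annotations
#'
#' An annotation set is a tibble with one row per labelled polygon:
#' `label` (character), `tissue_class` (`"tumour"` or `"control"`),
#' `anchor_frame` (0-based frame the polygon was drawn on — in practice the
#' frame preceding fluorescence onset), and `polygon` (list-column of
#' `n x 2` vertex matrices, 0-based pixel coordinates).
#'
#' @param label Character label, e.g. `"T1"`.
#' @param tissue_class `"tumour"` or `"control"`.
#' @param anchor_frame 0-based integer frame index.
#' @param polygon Vertex matrix or list of `c(x, y)` pairs (>= 3 vertices,
#'   simple).
#' @return One-row annotation tibble.
#' @export
roi_annotation <- function(label, tissue_class, anchor_frame, polygon) {
  if (!tissue_class %in% c("tumour", "control")) {
    abort(sprintf("unknown tissue_class '%s' (expected 'tumour' or 'control')",
                  tissue_class),
          class = "fluotrack_validation_error")
  }
  polygon <- as_polygon(polygon)
  validate_polygon(polygon)
  tibble::tibble(label = as.character(label),
                 tissue_class = tissue_class,
                 anchor_frame = as.integer(anchor_frame),
                 polygon = list(polygon))
}

#' Validate annotations against frame bounds
#'
#' Checks every polygon for >= 3 vertices, simplicity, and (when frame
#' dimensions are supplied) containment of all vertices within the frame.
#'
#' @param annotations Annotation tibble.
#' @param frame_dim Optional `c(height, width)` for the bounds check.
#' @return The annotations, invisibly; aborts on violation.
#' @export
validate_annotations <- function(annotations, frame_dim = NULL) {
  stopifnot(is.data.frame(annotations))
  for (i in seq_len(nrow(annotations))) {
    if (!annotations$tissue_class[i] %in% c("tumour", "control")) {
      abort(sprintf("row %d: unknown tissue_class '%s'", i,
                    annotations$tissue_class[i]),
            class = "fluotrack_validation_error")
    }
    poly <- as_polygon(annotations$polygon[[i]])
    validate_polygon(poly)
    if (!is.null(frame_dim)) {
      h <- frame_dim[1]; w <- frame_dim[2]
      if (any(poly[, 1] < 0 | poly[, 1] > w - 1 | poly[, 2] < 0 | poly[, 2] > h - 1)) {
        abort(sprintf(
          "row %d ('%s'): polygon vertex outside %d x %d frame bounds",
          i, annotations$label[i], h, w),
          class = "fluotrack_validation_error")
      }
    }
  }
  invisible(annotations)
}

#' Read and write ROI annotation files
#'
#' JSON on disk:
#' `{"annotations": [{"label": "...", "tissue_class": "tumour",
#' "anchor_frame": 0, "polygon": [[x, y], ...]}, ...]}`.
#' `read_annotations()` after `write_annotations()` is the identity on valid
#' annotation sets.
#'
#' @param path File path.
#' @param annotations Annotation tibble (see [roi_annotation()]).
#' @return `read_annotations()` returns the annotation tibble.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: '%s'", path),
          class = "fluotrack_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  items <- raw$annotations
  if (is.null(items)) {
    abort(sprintf("'%s' has no 'annotations' field", path),
          class = "fluotrack_io_error")
  }
  purrr::map_dfr(items, function(a) {
    poly <- a$polygon
    if (is.list(poly)) poly <- do.call(rbind, lapply(poly, as.numeric))
    roi_annotation(a$label, a$tissue_class, a$anchor_frame, poly)
  })
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  items <- purrr::pmap(annotations, function(label, tissue_class, anchor_frame,
                                             polygon, ...) {
    list(label = label, tissue_class = tissue_class,
         anchor_frame = anchor_frame,
         polygon = lapply(seq_len(nrow(polygon)),
                          function(i) c(polygon[i, 1], polygon[i, 2])))
  })
  jsonlite::write_json(list(annotations = items), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
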