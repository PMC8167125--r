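#' Polygon utilities
#'
#' Polygons are `n x 2` numeric matrices of 0-based pixel coordinates
#' (columns `x`, `y`; origin at the top-left pixel center, x rightward,
#' y downward). The last vertex connects implicitly back to the first.
#'
#' @param polygon An `n x 2` numeric matrix of vertices, `n >= 3`.
#' @name polygon-utils
NULL

as_polygon <- function(polygon) {
  if (is.list(polygon) && !is.data.frame(polygon)) {
    polygon <- do.call(rbind, lapply(polygon, as.numeric))
  }
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  dimnames(polygon) <- list(NULL, c("x", "y"))
  polygon
}

seg_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' @describeIn polygon-utils Check that a polygon has at least three vertices
#'   and is simple (no two non-adjacent edges cross). Returns the polygon
#'   matrix invisibly; aborts otherwise.
#' @export
validate_polygon <- function(polygon) {
  polygon <- as_polygon(polygon)
  n <- nrow(polygon)
  if (n < 3) {
    abort(sprintf("polygon must have >= 3 vertices, got %d", n),
          class = "fluotrack_validation_error")
  }
  if (!all(is.finite(polygon))) {
    abort("polygon vertices must be finite", class = "fluotrack_validation_error")
  }
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      # skip adjacent edges (they share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (seg_intersect(polygon[edges[i, 1], ], polygon[edges[i, 2], ],
                        polygon[edges[j, 1], ], polygon[edges[j, 2], ])) {
        abort("polygon is self-intersecting", class = "fluotrack_validation_error")
      }
    }
  }
  invisible(polygon)
}

#' @describeIn polygon-utils Signed shoelace area (positive for
#'   counter-clockwise vertex order in the image coordinate frame).
#' @export
polygon_area <- function(polygon) {
  p <- as_polygon(polygon)
  x <- p[, 1]; y <- p[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

#' @describeIn polygon-utils Vertex centroid.
#' @export
polygon_centroid <- function(polygon) {
  colMeans(as_polygon(polygon))
}

#' @describeIn polygon-utils Rasterized intersection-over-union of two
#'   polygons (pixel-center even-odd rule on the bounding grid).
#' @param polygon_b Second polygon for [polygon_iou()].
#' @export
polygon_iou <- function(polygon, polygon_b) {
  a <- as_polygon(polygon); b <- as_polygon(polygon_b)
  all_x <- c(a[, 1], b[, 1]); all_y <- c(a[, 2], b[, 2])
  # shift both into a non-negative frame before rasterizing
  ox <- floor(min(all_x)) - 1; oy <- floor(min(all_y)) - 1
  w <- ceiling(max(all_x)) - ox + 2
  h <- ceiling(max(all_y)) - oy + 2
  ma <- cpp_polygon_mask(h, w, a[, 1] - ox, a[, 2] - oy)
  mb <- cpp_polygon_mask(h, w, b[, 1] - ox, b[, 2] - oy)
  un <- sum(ma | mb)
  if (un == 0) return(NA_real_)
  sum(ma & mb) / un
}

#' Mask of pixels enclosed by a polygon
#'
#' Even-odd rule on pixel centers: pixel (x, y) belongs to the region when
#' its center lies inside the polygon.
#'
#' @param polygon Vertex matrix (see [validate_polygon()]).
#' @param dim Frame dimensions `c(height, width)` in pixels.
#' @return Logical `height x width` matrix.
#' @export
polygon_mask <- function(polygon, dim) {
  p <- as_polygon(polygon)
  cpp_polygon_mask(as.integer(dim[1]), as.integer(dim[2]), p[, 1], p[, 2])
}

# --- similarity transforms ---------------------------------------------------

# A similarity transform is the 4-vector (a, b, tx, ty):
#   x' = a*x - b*y + tx,  y' = b*x + a*y + ty
# i.e. scale s = sqrt(a^2 + b^2), rotation theta = atan2(b, a).

similarity_params <- function(scale = 1, theta = 0, tx = 0, ty = 0) {
  c(a = scale * cos(theta), b = scale * sin(theta), tx = tx, ty = ty)
}

apply_similarity <- function(params, xy) {
  xy <- as_polygon(xy)
  a <- params[1]; b <- params[2]
  cbind(x = a * xy[, 1] - b * xy[, 2] + params[3],
        y = b * xy[, 1] + a * xy[, 2] + params[4])
}

invert_similarity <- function(params) {
  a <- params[1]; b <- params[2]
  s2 <- a * a + b * b
  ai <- a / s2; bi <- -b / s2
  c(a = ai, b = bi,
    tx = -(ai * params[3] - bi * params[4]),
    ty = -(bi * params[3] + ai * params[4]))
}

# Least-squares similarity fit from point correspondences (n x 2 each).
fit_similarity_ls <- function(from, to) {
  mf <- colMeans(from); mt <- colMeans(to)
  xf <- from[, 1] - mf[1]; yf <- from[, 2] - mf[2]
  xt <- to[, 1] - mt[1]; yt <- to[, 2] - mt[2]
  denom <- sum(xf^2 + yf^2)
  if (denom < .Machine$double.eps) {
    # degenerate (coincident points): translation only
    return(c(a = 1, b = 0, tx = mt[1] - mf[1], ty = mt[2] - mf[2]))
  }
  a <- sum(xf * xt + yf * yt) / denom
  b <- sum(xf * yt - yf * xt) / denom
  c(a = a, b = b,
    tx = mt[1] - (a * mf[1] - b * mf[2]),
    ty = mt[2] - (b * mf[1] + a * mf[2]))
}

# Robust similarity: iteratively reweighted least squares with a residual
# cutoff at max(3 * median residual, min_cutoff_px). Returns the fit, the
# inlier mask and the inlier ratio; falls back to median translation when
# fewer than 3 inliers survive.
fit_similarity_robust <- function(from, to, min_cutoff_px = 1.0, iters = 3) {
  n <- nrow(from)
  inl <- rep(TRUE, n)
  fit <- fit_similarity_ls(from, to)
  for (i in seq_len(iters)) {
    pred <- apply_similarity(fit, from)
    res <- sqrt(rowSums((pred - to)^2))
    cutoff <- max(3 * median(res), min_cutoff_px)
    new_inl <- res <= cutoff
    if (sum(new_inl) < 3) break
    inl <- new_inl
    fit <- fit_similarity_ls(from[inl, , drop = FALSE], to[inl, , drop = FALSE])
  }
  if (sum(inl) < 3) {
    d <- to - from
    fit <- c(a = 1, b = 0, tx = median(d[, 1]), ty = median(d[, 2]))
    inl <- rep(TRUE, n)
    translation_only <- TRUE
  } else {
    translation_only <- FALSE
  }
  list(params = fit, inliers = inl, inlier_ratio = mean(inl),
       translation_only = translation_only)
}
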