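test_that("featureless regions yield no corners, with a warning not an error", {
  flat <- matrix(100, 80, 80)
  poly <- rbind(c(10, 10), c(70, 10), c(70, 70), c(10, 70))
  expect_warning(pts <- detect_features(flat, poly), "no detectable corners")
  expect_equal(nrow(pts), 0)
})

test_that("checkerboard corners are found at their true locations", {
  img <- make_checkerboard(100, 25)
  poly <- rbind(c(5, 5), c(95, 5), c(95, 95), c(5, 95))
  pts <- detect_features(img, poly, quality_level = 0.2, max_points = 20,
                         min_distance = 7)
  truth <- checkerboard_corners(100, 25)
  expect_equal(nrow(pts), 9)
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((truth$x - pts$x[i])^2 + (truth$y - pts$y[i])^2)
    expect_lte(min(d), 1)
  }
})

test_that("max_points keeps exactly the strongest corners (brute-force rank)", {
  img <- make_checkerboard(100, 25)
  poly <- rbind(c(5, 5), c(95, 5), c(95, 95), c(5, 95))
  # independent greedy selection over the response surface in plain R
  resp <- fluotrack:::cpp_min_eig_response(img)
  mask <- polygon_mask(poly, dim(img))
  cand <- which(mask & resp >= 0.2 * max(resp[mask]), arr.ind = TRUE)
  ord <- order(-resp[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, ]
  picked <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    xy <- c(cand[i, 2] - 1, cand[i, 1] - 1)
    if (nrow(picked) == 4) break
    if (nrow(picked) == 0 ||
        min((picked[, 1] - xy[1])^2 + (picked[, 2] - xy[2])^2) >= 49) {
      picked <- rbind(picked, xy)
    }
  }
  pts <- detect_features(img, poly, quality_level = 0.2, max_points = 4,
                         min_distance = 7)
  expect_equal(nrow(pts), 4)
  expect_equal(cbind(pts$x, pts$y), unname(picked))
  expect_true(all(diff(pts$response) <= 1e-12))
})

test_that("identical frames track with zero displacement", {
  img <- make_texture(120, 160)
  pts <- detect_features(img, rbind(c(20, 20), c(140, 20), c(140, 100), c(20, 100)),
                         max_points = 30)
  out <- track_step(img, img, pts)
  expect_true(all(out$valid))
  expect_lt(max(abs(out$x - pts$x)), 1e-6)
  expect_lt(max(abs(out$y - pts$y)), 1e-6)
})

test_that("a pure 3-pixel translation is recovered within half a pixel", {
  img <- make_texture(150, 200)
  shifted <- img
  shifted[, 4:200] <- img[, 1:197]      # content moves +3 px in x
  poly <- rbind(c(40, 40), c(160, 40), c(160, 110), c(40, 110))
  pts <- detect_features(img, poly, max_points = 40)
  out <- track_step(img, shifted, pts)
  dx <- median(out$x[out$valid] - pts$x[out$valid])
  dy <- median(out$y[out$valid] - pts$y[out$valid])
  expect_lt(abs(dx - 3), 0.5)
  expect_lt(abs(dy), 0.5)
})

test_that("uncorrelated frames invalidate points via the forward-backward check", {
  img <- make_texture(150, 200, seed = 1)
  noise <- withr::with_seed(2, matrix(runif(150 * 200, 0, 255), 150, 200))
  poly <- rbind(c(40, 40), c(160, 40), c(160, 110), c(40, 110))
  pts <- detect_features(img, poly, max_points = 40)
  out <- track_step(img, noise, pts)
  expect_gte(mean(!out$valid), 0.9)
})

test_that("frame size mismatch is rejected", {
  img <- make_texture(50, 60)
  pts <- tibble::tibble(point_id = 1L, x = 30, y = 25, valid = TRUE)
  expect_error(track_step(img, img[1:40, ], pts),
               class = "fluotrack_validation_error")
})

test_that("roi propagation is exact for translations and rotations", {
  poly <- rbind(c(10, 10), c(50, 10), c(50, 40), c(10, 40))
  withr::with_seed(9, {
    from <- cbind(runif(20, 10, 50), runif(20, 10, 40))
  })
  # pure translation
  corr <- data.frame(x_from = from[, 1], y_from = from[, 2],
                     x_to = from[, 1] + 5, y_to = from[, 2] - 2)
  moved <- propagate_roi(poly, corr)
  expect_equal(unname(moved[, 1]), poly[, 1] + 5, tolerance = 1e-9)
  expect_equal(unname(moved[, 2]), poly[, 2] - 2, tolerance = 1e-9)

  # 10-degree rotation about the centroid, vs analytic vertex rotation
  cen <- polygon_centroid(poly)
  th <- 10 * pi / 180
  rot <- function(m) {
    cbind(cos(th) * (m[, 1] - cen[1]) - sin(th) * (m[, 2] - cen[2]) + cen[1],
          sin(th) * (m[, 1] - cen[1]) + cos(th) * (m[, 2] - cen[2]) + cen[2])
  }
  corr_rot <- data.frame(x_from = from[, 1], y_from = from[, 2],
                         x_to = rot(from)[, 1], y_to = rot(from)[, 2])
  moved_rot <- propagate_roi(poly, corr_rot)
  expect_lt(max(abs(moved_rot - rot(poly))), 0.5)

  # gross outliers leave the estimate essentially unchanged
  corr_bad <- rbind(corr, data.frame(x_from = c(11, 12), y_from = c(11, 12),
                                     x_to = c(400, -300), y_to = c(-300, 500)))
  moved_bad <- propagate_roi(poly, corr_bad)
  expect_lt(max(abs(moved_bad - moved)), 0.5)

  # too few correspondences raise the tracking-lost signal
  expect_error(propagate_roi(poly, corr[1:2, ]),
               class = "fluotrack_tracking_lost")
})

test_that("polygon area scales with the square of the estimated scale", {
  poly <- rbind(c(10, 10), c(50, 10), c(50, 40), c(10, 40))
  from <- withr::with_seed(3, cbind(runif(15, 10, 50), runif(15, 10, 40)))
  s <- 1.07
  corr <- data.frame(x_from = from[, 1], y_from = from[, 2],
                     x_to = from[, 1] * s, y_to = from[, 2] * s)
  moved <- propagate_roi(poly, corr)
  ratio <- abs(polygon_area(moved)) / abs(polygon_area(poly))
  expect_equal(ratio, s^2, tolerance = 0.01)
})

test_that("a static scene tracks with constant polygons and no gaps", {
  sv <- simulate_video(make_scene(duration_s = 2, moving = FALSE))
  res <- run_tracking(sv$stream, scene_annotations(both = FALSE))
  r <- res$lesion
  expect_equal(nrow(r$gaps), 0)
  expect_equal(r$censored_s, 0)
  for (k in 0:(sv$stream$n_frames - 1)) {
    expect_lt(max(abs(r$polygons[[k + 1]] - default_lesion_poly())), 0.05)
  }
})

test_that("tracking is deterministic for identical inputs", {
  sv <- simulate_video(make_scene(duration_s = 1.5, moving = TRUE,
                                  noise_sd_gu = 1))
  ann <- scene_annotations(both = FALSE)
  r1 <- run_tracking(sv$stream, ann)$lesion
  r2 <- run_tracking(sv$stream, ann)$lesion
  expect_identical(r1$polygons, r2$polygons)
  expect_identical(r1$point_tracks, r2$point_tracks)
})

test_that("manual re-annotation closes a gap at its anchor frame", {
  n <- 90                               # 3 s at 30 fps
  occ <- list(c(30, 59))
  sv <- simulate_video(make_scene(duration_s = 3, moving = FALSE,
                                  occlusions = occ))
  ann <- dplyr::bind_rows(
    roi_annotation("lesion", "tumour", 0, default_lesion_poly()),
    roi_annotation("lesion", "tumour", 60, default_lesion_poly()))
  res <- run_tracking(sv$stream, ann)$lesion
  expect_equal(nrow(res$gaps), 1)
  expect_equal(res$gaps$start_frame, 30L)
  expect_equal(res$gaps$end_frame, 59L)
  expect_equal(res$reinit_frames, 60L)
  expect_equal(res$censored_s, 1)
})

test_that("anchor frames beyond the stream are rejected", {
  sv <- simulate_video(make_scene(duration_s = 0.5, moving = FALSE))
  bad <- roi_annotation("late", "tumour", 999, default_lesion_poly())
  expect_error(run_tracking(sv$stream, bad), class = "fluotrack_validation_error")
})
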