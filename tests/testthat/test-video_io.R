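test_that("side-by-side frames split at half width and re-join exactly", {
  img <- array(runif(60 * 200 * 3, 0, 255), dim = c(60, 200, 3))
  halves <- split_side_by_side(img, "side_by_side_lr")
  expect_equal(dim(halves$rgb), c(60, 100, 3))
  expect_identical(join_side_by_side(halves$rgb, halves$nir_raw,
                                     "side_by_side_lr"), img)
  swapped <- split_side_by_side(img, "side_by_side_rl")
  expect_identical(swapped$rgb, halves$nir_raw)
  expect_error(split_side_by_side(img[, 1:199, ]), class = "fluotrack_layout_error")
})

test_that("streams expose frame pairs with time_s = index / fps", {
  frames <- lapply(1:5, function(i) array(i, dim = c(20, 40, 3)))
  cfg <- stream_config(frames, layout = "side_by_side_lr", fps = 30)
  st <- load_stream(cfg)
  expect_equal(st$n_frames, 5)
  for (k in 0:4) {
    fp <- get_frame(st, k)
    expect_identical(fp$time_s, k / 30)
    expect_equal(dim(fp$rgb), c(20, 20, 3))
    expect_equal(dim(fp$nir), c(20, 20))
  }
  cfg60 <- stream_config(frames, layout = "side_by_side_lr", fps = 30,
                         downsample_fps = 10)
  st60 <- load_stream(cfg60)
  expect_equal(st60$n_frames, 2)        # frames 0 and 3
  expect_equal(get_frame(st60, 1)$time_s, 0.1)
})

test_that("nir conversion supports luma, green and max channel", {
  img <- array(0, dim = c(2, 2, 3))
  img[, , 1] <- 100; img[, , 2] <- 50; img[, , 3] <- 200
  expect_equal(nir_convert(img, "luma")[1, 1],
               0.299 * 100 + 0.587 * 50 + 0.114 * 200)
  expect_equal(nir_convert(img, "green_channel")[1, 1], 50)
  expect_equal(nir_convert(img, "max_channel")[1, 1], 200)
})

test_that("single_nir layout replicates the grey channel into rgb", {
  frames <- lapply(1:3, function(i) matrix(i * 10, 15, 25))
  st <- load_stream(stream_config(frames, layout = "single_nir", fps = 5))
  fp <- get_frame(st, 2)
  expect_equal(fp$nir, matrix(30, 15, 25))
  expect_equal(fp$rgb[, , 2], fp$nir)
})

test_that("two_files layout requires matching frame counts", {
  a <- lapply(1:3, function(i) array(i, dim = c(10, 10, 3)))
  b <- lapply(1:2, function(i) matrix(i, 10, 10))
  expect_error(load_stream(stream_config(list(a, b), layout = "two_files", fps = 1)),
               class = "fluotrack_sync_error")
  st <- load_stream(stream_config(list(a, a[1:3]), layout = "two_files", fps = 1))
  expect_equal(st$n_frames, 3)
})

test_that("PNG frame directories round-trip NIR within 1 grey unit", {
  skip_if_not_installed("png")
  dir <- withr::local_tempdir()
  sv <- simulate_video(make_scene(duration_s = 0.2, fps = 30, moving = FALSE,
                                  noise_sd_gu = 1))
  n <- sv$stream$n_frames
  for (k in seq(0, n - 1)) {
    fp <- get_frame(sv$stream, k)
    side <- join_side_by_side(fp$rgb, as_rgb(fp$nir), "side_by_side_lr")
    png::writePNG(side / 255, file.path(dir, sprintf("frame_%04d.png", k)))
  }
  st <- load_stream(stream_config(dir, layout = "side_by_side_lr", fps = 30))
  expect_equal(st$n_frames, n)
  for (k in seq(0, n - 1)) {
    diff <- abs(get_frame(st, k)$nir - get_frame(sv$stream, k)$nir)
    expect_lte(mean(diff), 1)
  }
  expect_error(load_stream(stream_config(file.path(dir, "missing"),
                                         layout = "single_nir", fps = 30)),
               class = "fluotrack_io_error")
})

test_that("annotations round-trip through JSON and are validated", {
  path <- withr::local_tempfile(fileext = ".json")
  ann <- dplyr::bind_rows(
    roi_annotation("T1", "tumour", 0, rbind(c(0, 0), c(10, 0), c(0, 10))),
    roi_annotation("C1", "control", 4,
                   rbind(c(20, 20), c(40, 22), c(43, 41), c(18, 39))))
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back$label, ann$label)
  expect_equal(back$tissue_class, ann$tissue_class)
  expect_equal(back$anchor_frame, ann$anchor_frame)
  expect_equal(back$polygon, ann$polygon)

  expect_error(roi_annotation("T", "tumour", 0, rbind(c(0, 0), c(1, 1))),
               class = "fluotrack_validation_error")
  expect_error(roi_annotation("T", "lesion", 0, rbind(c(0, 0), c(1, 0), c(0, 1))),
               class = "fluotrack_validation_error")
  bad <- roi_annotation("T", "tumour", 0, rbind(c(-1, 5), c(10, 0), c(0, 10)))
  expect_error(validate_annotations(bad, frame_dim = c(100, 100)),
               class = "fluotrack_validation_error")
  expect_silent(validate_annotations(ann, frame_dim = c(100, 100)))
})

test_that("trace CSV round-trips losslessly, including the empty trace", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- intensity_trace(numeric(0), numeric(0), integer(0), logical(0))
  write_trace(empty, path)
  expect_identical(readLines(path)[1], "time_s,intensity_gu,n_pixels,gap_flag")
  expect_equal(nrow(read_trace(path)), 0)

  small <- intensity_trace(c(0, 0.5, 1), c(10.25, NA, 30.125),
                           c(100L, 0L, 100L), c(FALSE, TRUE, FALSE))
  write_trace(small, path)
  expect_equal(length(readLines(path)), 4)
  back <- read_trace(path)
  expect_equal(back$time_s, small$time_s)
  expect_equal(back$intensity_gu, small$intensity_gu)
  expect_equal(back$gap_flag, small$gap_flag)

  # long high-rate trace (10 min at 30 fps)
  n <- 18000
  long <- withr::with_seed(5, intensity_trace(
    (seq_len(n) - 1) / 30, runif(n, 0, 255),
    sample(50:200, n, replace = TRUE), rep(FALSE, n)))
  write_trace(long, path)
  back <- read_trace(path)
  expect_lt(max(abs(back$intensity_gu - long$intensity_gu)), 1e-6)
  expect_lt(max(abs(back$time_s - long$time_s)), 1e-6)

  writeLines(c("time_s,intensity_gu,n_pixels,gap_flag",
               "1,10,5,0", "0.5,11,5,0"), path)
  expect_error(read_trace(path), class = "fluotrack_format_error")
})

test_that("randomized annotation and trace instances round-trip (property)", {
  for (i in 1:10) {
    withr::with_seed(100 + i, {
      k <- sample(3:8, 1)
      # star-shaped construction guarantees a simple polygon
      ang <- sort(runif(k, 0, 2 * pi))
      rad <- runif(k, 5, 30)
      poly <- cbind(50 + rad * cos(ang), 50 + rad * sin(ang))
      ann <- roi_annotation(paste0("R", i),
                            sample(c("tumour", "control"), 1),
                            sample(0:100, 1), poly)
      pa <- withr::local_tempfile(fileext = ".json")
      write_annotations(ann, pa)
      expect_equal(read_annotations(pa)$polygon, ann$polygon)

      m <- sample(2:50, 1)
      tr <- intensity_trace(cumsum(runif(m, 0.1, 1)), runif(m, 0, 255))
      pt <- withr::local_tempfile(fileext = ".csv")
      write_trace(tr, pt)
      back <- read_trace(pt)
      expect_lt(max(abs(back$intensity_gu - tr$intensity_gu)), 1e-6)
    })
  }
})

test_that("trace decimation reproduces the low-rate sampling regime", {
  n <- 10 * 30 + 1                      # 10 s at 30 fps
  tr <- intensity_trace((seq_len(n) - 1) / 30, rep(100, n), fps_effective = 30)
  down <- downsample_trace(tr, 1)
  expect_equal(nrow(down), 11)          # floor(duration) + 1
  expect_equal(attr(down, "fps_effective"), 1)
  expect_error(downsample_trace(down, 30), class = "fluotrack_validation_error")
})
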