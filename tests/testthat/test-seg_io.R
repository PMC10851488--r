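test_that("segline files round-trip through both dialects", {
  set.seed(42)
  depth <- 1 + cumsum(rnorm(643, 0, 1e-3))
  depth[c(5, 300:310)] <- NA
  ln <- segline(depth, px_h = 0.014, eye_id = "rt01", scan_angle_deg = 15)

  fj <- withr::local_tempfile(fileext = ".json")
  write_segline(ln, fj)
  lj <- load_segline(fj)
  expect_identical(lj$depth_mm, ln$depth_mm)       # bit-exact JSON
  expect_identical(lj$px_h, ln$px_h)
  expect_identical(lj$eye_id, "rt01")
  expect_identical(lj$scan_angle_deg, 15)

  fc <- withr::local_tempfile(fileext = ".csv")
  write_segline(ln, fc)
  lc <- load_segline(fc)
  expect_equal(lc$depth_mm, ln$depth_mm, tolerance = 1e-6)
  expect_identical(is.na(lc$depth_mm), is.na(ln$depth_mm))
  expect_identical(lc$n_cols, 643L)
  expect_identical(lc$x_mm, ln$x_mm)
})

test_that("seglines over the 20% missing cap are rejected at load and construction", {
  depth <- rep(1, 643)
  depth[1:200] <- NA                                # 31% missing
  expect_error(segline(depth, px_h = 0.014), class = "mcindex_validation_error")
  good <- segline(rep(1, 643), px_h = 0.014)
  f <- withr::local_tempfile(fileext = ".csv")
  write_segline(good, f)
  rows <- readLines(f)
  rows[6:206] <- sub(",.*$", ",", rows[6:206])      # blank out 201 depths
  writeLines(rows, f)
  expect_error(load_segline(f), class = "mcindex_validation_error")
  expect_error(load_segline(withr::local_tempfile(fileext = ".csv")),
               class = "mcindex_format_error")
})

test_that("non-uniform column spacing in a segline CSV is a format error", {
  ln <- segline(seq(1, 1.1, length.out = 320), px_h = 0.014)
  f <- withr::local_tempfile(fileext = ".csv")
  write_segline(ln, f)
  rows <- readLines(f)
  writeLines(rows[-10], f)                          # drop one body row
  expect_error(load_segline(f), class = "mcindex_format_error")
})

test_that("corrections replace exactly their spans and stamp the source", {
  ln <- segline(rep(1, 643), px_h = 0.014, eye_id = "c1")
  expect_identical(apply_corrections(ln, correction_overlay(list())), ln)

  ov <- correction_overlay(list(list(col_start = 100, col_end = 110,
                                     depths_mm = seq(2, 2.9, by = 0.1))))
  out <- apply_corrections(ln, ov)
  changed <- which(out$depth_mm != ln$depth_mm)
  expect_identical(changed, 101:110)                # 0-based [100,110)
  expect_identical(out$source, "corrected")
  expect_identical(out$n_cols, ln$n_cols)
  expect_identical(out$x_mm, ln$x_mm)

  expect_error(apply_corrections(ln, correction_overlay(list(
    list(col_start = 640, col_end = 650, depths_mm = rep(1, 10))))),
    class = "mcindex_validation_error")
  expect_error(correction_overlay(list(
    list(col_start = 0, col_end = 5, depths_mm = 1:5),
    list(col_start = 3, col_end = 8, depths_mm = 1:5))),
    class = "mcindex_validation_error")
  expect_error(correction_overlay(list(
    list(col_start = 0, col_end = 5, depths_mm = 1:4))),
    class = "mcindex_validation_error")
})

test_that("correction overlays load from their JSON interchange form", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"col_start": 2, "col_end": 4, "depths_mm": [1.5, 1.6]}]', f)
  ov <- load_overlay(f)
  ln <- apply_corrections(segline(rep(1, 320), px_h = 0.014), ov)
  expect_equal(ln$depth_mm[3:4], c(1.5, 1.6))
})

test_that("gap interpolation is linear inside, nearest at the edges, and shape-preserving", {
  z <- c(NA, NA, 0.5, 0.6, NA, NA, NA, 1.00, NA, NA, NA, 1.04, 0.9)
  ln <- segline(c(z, rep(1, 300)), px_h = 0.01)
  out <- interpolate_gaps(ln)
  expect_false(anyNA(out$depth_mm))
  expect_equal(out$depth_mm[1:2], c(0.5, 0.5))            # leading extension
  expect_equal(out$depth_mm[9:11], c(1.01, 1.02, 1.03))   # linear fill
  expect_identical(out$n_cols, ln$n_cols)
  expect_identical(out$x_mm, ln$x_mm)
  expect_identical(interpolate_gaps(out), out)            # no-gap identity
})

test_that("B-scan reading enforces pitch metadata and grayscale format", {
  img16 <- matrix(runif(992 * 643), 992, 643)
  ft <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(img16, ft, bits.per.sample = 16L)
  b <- read_bscan(ft, px_h = 0.014, px_v = 0.0026, scan_angle_deg = 0,
                  eye_id = "e1")
  expect_s3_class(b, "bscan_image")
  expect_identical(ncol(b$pixels), 643L)
  expect_equal(b$scan_len_mm, 9.002)
  expect_true(all(b$pixels >= 0 & b$pixels <= 1))

  expect_error(read_bscan(ft, px_h = 0.014, px_v = NULL),
               class = "mcindex_config_error")
  expect_error(read_bscan(ft, px_h = 0.014),
               class = "mcindex_config_error")
  expect_error(read_bscan(ft, px_h = 0.014, px_v = 0.0026, scan_len_mm = 10),
               class = "mcindex_config_error")

  fp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(992 * 643 * 3), c(992, 643, 3)), fp)
  expect_error(read_bscan(fp, px_h = 0.014, px_v = 0.0026),
               class = "mcindex_format_error")
})

test_that("RPE detection recovers rendered lines and fails loudly on empty scans", {
  spec <- phantom_spec(rho_mm = 11, bump_A_mm = 0.3, bump_sigma_mm = 1.3)
  ln <- phantom_line(spec, 30)

  det <- detect_rpe_line(render_bscan(ln, spec))
  expect_identical(det$source, "detected")
  expect_lt(max(abs(det$depth_mm - ln$depth_mm)), spec$px_v / 2)

  noisy <- phantom_spec(rho_mm = 11, bump_A_mm = 0.3, bump_sigma_mm = 1.3,
                        noise_sigma = 0.08, seed = 7)
  detn <- detect_rpe_line(render_bscan(ln, noisy))
  err <- abs(detn$depth_mm - ln$depth_mm)
  expect_lte(stats::median(err, na.rm = TRUE), spec$px_v)
  expect_gte(mean(err <= 2 * spec$px_v, na.rm = TRUE), 0.95)

  blank <- new_bscan_image(matrix(0, 400, 643), px_h = 0.014, px_v = 0.0026)
  expect_error(detect_rpe_line(blank), class = "mcindex_detection_error")
})
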