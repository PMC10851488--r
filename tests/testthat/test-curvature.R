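test_that("circumradius matches closed forms and the bisector oracle", {
  expect_equal(circumradius(c(0, 0), c(1, 0), c(0, 1)), sqrt(2) / 2)
  expect_equal(circumradius(c(0, 0), c(1, 0), c(0, 1)),
               oracle_circumradius(c(0, 0), c(1, 0), c(0, 1)))

  th <- c(0.3, 1.1, 2.0)
  pts <- lapply(th, function(t) 8.44 * c(cos(t), sin(t)))
  expect_equal(circumradius(pts[[1]], pts[[2]], pts[[3]]), 8.44)

  expect_identical(circumradius(c(0, 0), c(1, 0), c(2, 0)), Inf)
  expect_error(circumradius(c(0, 0), c(0, 0), c(1, 1)),
               class = "mcindex_validation_error")

  set.seed(3)
  for (i in 1:25) {
    p <- matrix(rnorm(6, sd = 5), 2)
    expect_equal(circumradius(p[, 1], p[, 2], p[, 3]),
                 oracle_circumradius(p[, 1], p[, 2], p[, 3]),
                 tolerance = 1e-10)
  }
})

test_that("circumradius is invariant under rotation and translation", {
  set.seed(11)
  for (i in 1:20) {
    p <- matrix(rnorm(6, sd = 4), 2)
    r0 <- circumradius(p[, 1], p[, 2], p[, 3])
    th <- runif(1, 0, 2 * pi)
    Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    t <- rnorm(2, sd = 10)
    q <- Q %*% p + t
    expect_equal(circumradius(q[, 1], q[, 2], q[, 3]), r0, tolerance = 1e-9)
  }
})

test_that("ROI bounds exclude the configured margins", {
  expect_identical(roi_bounds(segline(rep(1, 643), 0.014), 100L),
                   c(100L, 542L))
  expect_identical(roi_bounds(segline(rep(1, 201), 0.014), 100L),
                   c(100L, 100L))
  expect_error(roi_bounds(segline(rep(1, 200), 0.014), 100L),
               class = "mcindex_validation_error")
})

test_that("profiles on circle-sampled lines return the circle radius everywhere", {
  for (rho in c(8.4375, 12)) {
    prof <- curvature_profile(circle_line(rho, n = 643, px_h = 0.014))
    roi_vals <- prof$radius_mm[(prof$roi[1]:prof$roi[2]) + 1L]
    expect_false(anyNA(roi_vals))
    expect_lt(max(abs(roi_vals - rho)), 1e-9)
    expect_equal(prof$r_min_mm, rho, tolerance = 1e-9)
    expect_identical(prof$chord_offset_cols, 100L)
    expect_identical(prof$roi, c(100L, 542L))
  }
})

test_that("cocircularity holds across random radii, pitches and offsets", {
  set.seed(101)
  for (i in 1:20) {
    px_h <- runif(1, 0.008, 0.02)
    k <- round(1.4 / px_h)
    n <- sample((2 * k + 41):643, 1)               # room for the chord margins
    width <- (n - 1) * px_h
    rho <- runif(1, max(5, width / 2 + 1.5), 50)   # arc must span the scan
    xc <- width / 2 + runif(1, -1, 1)
    ln <- circle_line(rho, n = n, px_h = px_h, xc = xc,
                      zc = rho + runif(1, 0.2, 2))
    prof <- curvature_profile(ln, margin_cols = k)
    vals <- prof$radius_mm[!is.na(prof$radius_mm)]
    expect_lt(max(abs(vals - rho) / rho), 1e-6)
  }
})

test_that("a flat line is flagged with the infinite-radius sentinel", {
  prof <- curvature_profile(segline(rep(1, 643), 0.014))
  expect_true(prof$flagged)
  expect_identical(prof$r_min_mm, Inf)
  expect_true(all(is.infinite(
    prof$radius_mm[(prof$roi[1]:prof$roi[2]) + 1L])))
})

test_that("profiles scale exactly with the coordinates (similarity)", {
  ln <- circle_line(10, n = 401, px_h = 0.014)
  base <- curvature_profile(ln, margin_cols = 100L)
  for (s in c(2, 0.5)) {       # powers of two: scaling is exact in floats
    scaled <- segline(ln$depth_mm * s, px_h = ln$px_h * s,
                      eye_id = ln$eye_id, scan_angle_deg = ln$scan_angle_deg)
    prof_s <- curvature_profile(scaled, chord_offset_mm = 1.4 * s,
                                margin_cols = 100L)
    expect_identical(prof_s$radius_mm, base$radius_mm * s)
    expect_identical(prof_s$r_min_col, base$r_min_col)
  }
  s <- 1.7
  scaled <- segline(ln$depth_mm * s, px_h = ln$px_h * s)
  prof_s <- curvature_profile(scaled, chord_offset_mm = 1.4 * s,
                              margin_cols = 100L)
  expect_equal(prof_s$radius_mm, base$radius_mm * s, tolerance = 1e-12)
})

test_that("pitch-halving of a stretched raster representation is an exact no-op", {
  # depths held as (possibly sub-pixel) row positions; storing the raster
  # stretched (rows x2) with the pitch halved must reproduce the same mm
  # line, hence the same profile, bit for bit
  px_v <- 0.0026
  rows <- (1 + 0.1 * sin(seq(0, 3 * pi, length.out = 643))) / px_v
  d1 <- rows * px_v
  d2 <- (rows * 2) * (px_v / 2)
  expect_identical(d2, d1)
  p1 <- curvature_profile(segline(d1, 0.014))
  p2 <- curvature_profile(segline(d2, 0.014))
  expect_identical(p2$radius_mm, p1$radius_mm)
  expect_identical(p2$r_min_mm, p1$r_min_mm)
})

test_that("profiles agree with the brute-force solver on random toy lines", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(20:50, 1)
    px_h <- runif(1, 0.01, 0.05)
    x <- (seq_len(n) - 1) * px_h
    z <- 1 + 0.3 * sin(runif(1, 0.5, 3) * x + runif(1, 0, pi)) +
      0.05 * rnorm(n)
    ln <- segline(z, px_h = px_h)
    k <- sample(2:5, 1)
    prof <- curvature_profile(ln, chord_offset_mm = k * px_h, margin_cols = k)
    got <- prof$radius_mm[(prof$roi[1]:prof$roi[2]) + 1L]
    want <- oracle_profile(x, z, k, prof$roi[1], prof$roi[2])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the minimum radius never increases with bump amplitude", {
  r_mins <- vapply(seq(0, 0.5, by = 0.1), function(A) {
    sp <- phantom_spec(rho_mm = 12, bump_A_mm = A, bump_sigma_mm = 1.2)
    curvature_profile(phantom_line(sp, 0))$r_min_mm
  }, numeric(1))
  expect_true(all(diff(r_mins) <= 1e-12))
})

test_that("profile CSV export records the construction and the minimum", {
  prof <- curvature_profile(circle_line(12, n = 643, px_h = 0.014))
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# chord_offset_mm=1.4$", lines)))
  expect_true(any(grepl("^# roi=100,542$", lines)))
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  expect_identical(nrow(body), 443L)
  expect_equal(body$radius_mm, rep(12, 443), tolerance = 1e-6)

  flat <- curvature_profile(segline(rep(1, 643), 0.014))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(flat, f2)
  expect_true(any(grepl("inf", readLines(f2))))
})
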