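# Independent oracles, deliberately implemented by a different route than the
# package: the circumcenter is found by solving the perpendicular-bisector
# linear system, not by the side-product/area formula.

oracle_circumradius <- function(p1, p2, p3) {
  A <- rbind(2 * (p2 - p1), 2 * (p3 - p1))
  b <- c(sum(p2^2) - sum(p1^2), sum(p3^2) - sum(p1^2))
  if (abs(det(A)) < 1e-14) return(Inf)
  center <- solve(A, b)
  sqrt(sum((center - p1)^2))
}

# Brute-force three-point profile on a sampled line: plain loop, no package
# code. Returns radii for every column where both endpoints exist.
oracle_profile <- function(x, z, k, first0, last0) {
  vapply((first0:last0) + 1L, function(a) {
    oracle_circumradius(c(x[a - k], z[a - k]), c(x[a], z[a]),
                        c(x[a + k], z[a + k]))
  }, numeric(1))
}

# Continuous-curve three-point oracle for a phantom scan: evaluates the
# analytic wall depth (re-derived here, not taken from the package) at the
# three arc abscissae for every ROI column and minimizes the brute-force
# radius.
oracle_phantom_r_min <- function(rho, A, sigma, x0, depth_offset, n_cols,
                                 px_h, chord_mm, margin_cols) {
  half_w <- (n_cols - 1) * px_h / 2
  zf <- function(x) {
    depth_offset + sqrt(rho^2 - x^2) - sqrt(rho^2 - half_w^2) +
      if (A > 0) A * exp(-(x - x0)^2 / (2 * sigma^2)) else 0
  }
  k <- round(chord_mm / px_h)
  m <- max(margin_cols, k)
  xs <- (seq_len(n_cols) - 1 - (n_cols - 1) / 2) * px_h
  centers <- (m + 1):(n_cols - m)
  min(vapply(centers, function(a) {
    xa <- xs[a]; xb <- xs[a - k]; xc <- xs[a + k]
    oracle_circumradius(c(xb, zf(xb)), c(xa, zf(xa)), c(xc, zf(xc)))
  }, numeric(1)))
}

# A segline sampled exactly from a circle of radius rho: lower arc of the
# circle centered at (xc, zc), sampled at pitch px_h over n columns.
circle_line <- function(rho, n = 401, px_h = 0.014, xc = NULL, zc = NULL,
                        eye_id = "circle", angle = 0) {
  width <- (n - 1) * px_h
  stopifnot(width < 2 * rho)
  if (is.null(xc)) xc <- width / 2
  if (is.null(zc)) zc <- rho + 0.5
  x <- (seq_len(n) - 1) * px_h
  z <- zc - sqrt(rho^2 - (x - xc)^2)
  segline(z, px_h = px_h, eye_id = eye_id, scan_angle_deg = angle)
}
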