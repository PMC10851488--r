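#' Radius of the circle through three points
#'
#' The per-pixel "radius of arc": the circumradius
#' \eqn{R_c = \frac{|p_1p_2|\,|p_2p_3|\,|p_1p_3|}{4\,\mathrm{area}(p_1,p_2,p_3)}}
#' of the unique circle through three non-collinear points, in the same units
#' as the coordinates (mm throughout this package). Collinear triples (twice
#' the signed triangle area below `tol`, in mm^2) return `Inf`, the
#' infinite-radius sentinel, rather than a huge unstable number.
#'
#' @param p1,p2,p3 Numeric length-2 points `(x, y)` in mm.
#' @param tol Collinearity tolerance on twice the triangle area (mm^2).
#' @return The circumradius in mm, or `Inf` for collinear points.
#' @export
circumradius <- function(p1, p2, p3, tol = 1e-12) {
  if (identical(all.equal(p1, p2, tolerance = 0), TRUE) ||
      identical(all.equal(p2, p3, tolerance = 0), TRUE) ||
      identical(all.equal(p1, p3, tolerance = 0), TRUE))
    validation_error("circumradius: coincident points")
  circumradius_vec(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2], tol = tol)
}

# Vectorized three-point radius; cross = twice the signed triangle area.
circumradius_vec <- function(x1, y1, x2, y2, x3, y3, tol = 1e-12) {
  a <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  b <- sqrt((x2 - x3)^2 + (y2 - y3)^2)
  c <- sqrt((x1 - x3)^2 + (y1 - y3)^2)
  cross <- abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
  r <- ifelse(cross < tol, Inf, a * b * c / (2 * cross))
  r
}

#' Region-of-interest column bounds
#'
#' The ROI excludes `margin_cols` columns at each lateral edge of the scan
#' (the device's segmentation is unreliable at the edges and the arc
#' endpoints must exist for every evaluated column). Returns 0-based
#' inclusive bounds.
#'
#' @param line A [segline].
#' @param margin_cols Columns excluded at each edge (default 100).
#' @return Integer `c(first_col, last_col)`, 0-based inclusive.
#' @export
roi_bounds <- function(line, margin_cols = 100L) {
  margin_cols <- as.integer(margin_cols)
  if (line$n_cols <= 2L * margin_cols)
    validation_error(sprintf(
      "line with %d columns too short for a %d-column margin on each side",
      line$n_cols, margin_cols))
  c(margin_cols, line$n_cols - 1L - margin_cols)
}

#' Sliding three-point curvature profile of a segmentation line
#'
#' For every column `a` in the ROI, an arc is constructed through the line
#' point at `a` and the two points `chord_offset_cols` columns to each side
#' (1.4 mm, i.e. 100 columns at 0.014 mm/px, by default — so the full chord
#' spans 2.8 mm), and its circumradius is recorded. All geometry is computed
#' on physical `(x_mm, depth_mm)` coordinates: anisotropic pixel pitch and
#' any display stretch are absorbed by the mm conversion, never by
#' resampling, so no radius is ever computed in pixel units. The per-scan
#' minimum radius `r` is the smallest finite profile value (first column on
#' ties); columns whose three points are collinear carry the `Inf` sentinel
#' and are excluded from the minimum. A line that is collinear across the
#' whole ROI (flat wall) yields `r_min_mm = Inf` and is flagged, and such
#' scans are excluded from eye-level aggregation.
#'
#' @param line A gap-free [segline] (run [interpolate_gaps()] first).
#' @param chord_offset_mm Lateral distance from the evaluated column to each
#'   arc endpoint, mm; converted to columns by `round(chord_offset_mm/px_h)`,
#'   which must be >= 2.
#' @param margin_cols ROI margin; effective margin is
#'   `max(margin_cols, chord_offset_cols)` so both endpoints always exist.
#' @return An object of class `curvature_profile`: `radius_mm` (per-column,
#'   `NA` outside the ROI, `Inf` sentinel on collinear columns), `roi`
#'   (0-based inclusive bounds), `r_min_mm`, `r_min_col` (0-based),
#'   `chord_offset_cols`, `chord_offset_mm`, `flagged`, and the line's
#'   identifiers.
#' @export
curvature_profile <- function(line, chord_offset_mm = 1.4, margin_cols = 100L) {
  validate_segline(line)
  if (anyNA(line$depth_mm))
    validation_error("curvature_profile requires a gap-free line; run interpolate_gaps() first")
  if (chord_offset_mm <= 0)
    validation_error("chord_offset_mm must be positive")
  k <- as.integer(round(chord_offset_mm / line$px_h))
  if (k < 2L)
    validation_error(sprintf(
      "chord offset %.3g mm is under 2 columns at pitch %.4g mm/px",
      chord_offset_mm, line$px_h))
  margin <- max(as.integer(margin_cols), k)
  roi <- roi_bounds(line, margin)
  a <- (roi[1]:roi[2]) + 1L              # 1-based center indices
  x <- line$x_mm; z <- line$depth_mm
  rad <- circumradius_vec(x[a - k], z[a - k], x[a], z[a], x[a + k], z[a + k])
  radius_mm <- rep(NA_real_, line$n_cols)
  radius_mm[a] <- rad
  finite <- is.finite(rad)
  if (any(finite)) {
    r_min <- min(rad[finite])
    r_col <- a[which(rad == r_min)[1]] - 1L   # 0-based, first on ties
    flagged <- FALSE
  } else {
    r_min <- Inf; r_col <- NA_integer_; flagged <- TRUE
  }
  structure(list(radius_mm = radius_mm, roi = roi, r_min_mm = r_min,
                 r_min_col = r_col, chord_offset_cols = k,
                 chord_offset_mm = chord_offset_mm, flagged = flagged,
                 px_h = line$px_h, eye_id = line$eye_id,
                 scan_angle_deg = line$scan_angle_deg, n_cols = line$n_cols),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile> eye=%s angle=%s deg, ROI [%d, %d], chord +/-%d cols\n",
              x$eye_id, format(x$scan_angle_deg), x$roi[1], x$roi[2],
              x$chord_offset_cols))
  if (x$flagged) cat("  flat line: all ROI arcs collinear (r = Inf)\n")
  else cat(sprintf("  r = %.4f mm at column %d\n", x$r_min_mm, x$r_min_col))
  invisible(x)
}

#' Plot a curvature profile
#'
#' Radius of arc against lateral position over the ROI, with the minimum
#' marked — the working display for reading off where the wall is steepest.
#'
#' @param x A [curvature_profile()].
#' @param ... Passed to [plot()].
#' @export
plot.curvature_profile <- function(x, ...) {
  cols <- (x$roi[1]:x$roi[2]) + 1L
  xs <- (cols - 1) * x$px_h
  rs <- x$radius_mm[cols]
  graphics::plot(xs, rs, type = "l", xlab = "lateral position (mm)",
                 ylab = "radius of arc (mm)",
                 main = sprintf("eye %s, %s deg", x$eye_id,
                                format(x$scan_angle_deg)), ...)
  if (!x$flagged)
    graphics::points(x$r_min_col * x$px_h, x$r_min_mm, pch = 19, col = "red")
  invisible(x)
}

#' Export a curvature profile to CSV
#'
#' Comment header records the chord offset, ROI bounds and the minimum; body
#' is `col,x_mm,radius_mm` over ROI columns with `inf` for the collinear
#' sentinel.
#'
#' @param profile A [curvature_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  cols <- (profile$roi[1]:profile$roi[2])
  r <- profile$radius_mm[cols + 1L]
  hdr <- c(sprintf("# chord_offset_mm=%s", fmt_double(profile$chord_offset_mm)),
           sprintf("# roi=%d,%d", profile$roi[1], profile$roi[2]),
           sprintf("# r_min_mm=%s", if (is.finite(profile$r_min_mm))
             sprintf("%.9f", profile$r_min_mm) else "inf"),
           sprintf("# r_min_col=%s", format(profile$r_min_col)),
           "col,x_mm,radius_mm")
  rows <- sprintf("%d,%.9f,%s", cols, cols * profile$px_h,
                  ifelse(is.finite(r), sprintf("%.9f", r), "inf"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
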