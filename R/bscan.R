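#' Read an OCT B-scan image
#'
#' Loads a grayscale 8/16-bit TIFF or PNG B-scan (rows = depth, columns =
#' lateral position) with intensities normalized to `[0, 1]`. Physical pixel
#' pitches are required metadata and are never inferred from the image size:
#' every downstream radius is computed in mm, so a guessed pitch would corrupt
#' every result silently. `px_v` is the pitch of the stored raster — if the
#' file was exported with the display's 2x vertical elongation, pass the
#' elongated pitch (half the acquisition pitch): aspect correction is then a
#' coordinate conversion, not a resample.
#'
#' @param path Path to a TIFF or PNG file.
#' @param px_h Lateral pixel pitch, mm/pixel.
#' @param px_v Axial (depth) pixel pitch of the stored raster, mm/pixel.
#' @param scan_angle_deg Nominal radial-scan angle in degrees.
#' @param eye_id Opaque eye identifier.
#' @param scan_len_mm Nominal lateral scan length in mm; checked against
#'   `ncol * px_h` within 2% when supplied, otherwise derived.
#' @return An object of class `bscan_image` with fields `pixels` (matrix in
#'   `[0,1]`), `px_h`, `px_v`, `scan_angle_deg`, `eye_id`, `scan_len_mm`.
#' @seealso [detect_rpe_line()], [render_bscan()]
#' @export
read_bscan <- function(path, px_h, px_v, scan_angle_deg = NA_real_,
                       eye_id = "unknown", scan_len_mm = NULL) {
  if (missing(px_h) || is.null(px_h) || !is.finite(px_h) || px_h <= 0)
    config_error("read_bscan: lateral pitch px_h (mm/pixel) is required metadata")
  if (missing(px_v) || is.null(px_v) || !is.finite(px_v) || px_v <= 0)
    config_error("read_bscan: axial pitch px_v (mm/pixel) is required metadata")
  if (!file.exists(path)) format_error(paste("image not found:", path))
  lower <- tolower(path)
  px <- if (grepl("\\.tiff?$", lower)) {
    tryCatch(tiff::readTIFF(path), error = function(e)
      format_error(paste("cannot read TIFF:", conditionMessage(e))))
  } else if (grepl("\\.png$", lower)) {
    tryCatch(png::readPNG(path), error = function(e)
      format_error(paste("cannot read PNG:", conditionMessage(e))))
  } else format_error("read_bscan: expected a .tif/.tiff or .png file")
  if (length(dim(px)) == 3) {
    if (dim(px)[3] > 1) format_error("read_bscan: image is not grayscale")
    px <- px[, , 1]
  }
  if (!is.matrix(px)) format_error("read_bscan: image did not decode to a 2-D raster")
  new_bscan_image(px, px_h = px_h, px_v = px_v, scan_angle_deg = scan_angle_deg,
                  eye_id = eye_id, scan_len_mm = scan_len_mm)
}

new_bscan_image <- function(pixels, px_h, px_v, scan_angle_deg = NA_real_,
                            eye_id = "unknown", scan_len_mm = NULL) {
  if (nrow(pixels) < 2 || ncol(pixels) < 301)
    validation_error(sprintf(
      "bscan_image: raster %dx%d too small (need >= 2 rows, >= 301 columns for the ROI)",
      nrow(pixels), ncol(pixels)))
  derived <- ncol(pixels) * px_h
  if (!is.null(scan_len_mm)) {
    if (abs(scan_len_mm - derived) / derived > 0.02)
      config_error(sprintf(
        "scan_len_mm=%.3f inconsistent with %d cols x %.4g mm/px = %.3f mm (>2%%)",
        scan_len_mm, ncol(pixels), px_h, derived))
  } else scan_len_mm <- derived
  structure(list(pixels = pixels, px_h = px_h, px_v = px_v,
                 scan_angle_deg = as.numeric(scan_angle_deg),
                 eye_id = as.character(eye_id), scan_len_mm = scan_len_mm),
            class = "bscan_image")
}

#' @export
print.bscan_image <- function(x, ...) {
  cat(sprintf("<bscan_image> eye=%s angle=%s deg, %dx%d px @ (%.4g, %.4g) mm/px, %.2f mm scan\n",
              x$eye_id, format(x$scan_angle_deg), nrow(x$pixels), ncol(x$pixels),
              x$px_v, x$px_h, x$scan_len_mm))
  invisible(x)
}

#' Undo an integer display stretch
#'
#' OCT review software commonly presents B-scans elongated vertically (2x on
#' the device emulated here) by repeating rows. When a raster was stored in
#' that presentation form, this restores the acquisition raster exactly:
#' every `stretch`-th row is kept and the axial pitch is multiplied back by
#' `stretch`. For a duplicated-row stretch this is lossless (bit-identical
#' to the unstretched raster). Downstream geometry is computed in mm either
#' way — the stored pitch already makes the mm conversion correct — so this
#' step only matters when bit-level agreement with the unstretched raster is
#' wanted.
#'
#' @param img A `bscan_image` stored with an integer vertical stretch.
#' @param stretch The integer elongation factor (default 2).
#' @return A `bscan_image` on the acquisition raster.
#' @export
correct_aspect <- function(img, stretch = 2L) {
  stretch <- as.integer(stretch)
  if (stretch < 1) validation_error("correct_aspect: stretch must be >= 1")
  if (stretch == 1L) return(img)
  if (nrow(img$pixels) %% stretch != 0)
    validation_error(sprintf(
      "correct_aspect: %d rows not divisible by stretch %d",
      nrow(img$pixels), stretch))
  new_bscan_image(img$pixels[seq(1, nrow(img$pixels), by = stretch), ,
                             drop = FALSE],
                  px_h = img$px_h, px_v = img$px_v * stretch,
                  scan_angle_deg = img$scan_angle_deg, eye_id = img$eye_id,
                  scan_len_mm = img$scan_len_mm)
}

#' Detector tuning parameters
#'
#' @param smooth_halfwidth_cols Half-width (columns) of the cross-column
#'   rolling median applied to the detected depth series; default 5 (11-column
#'   window), wide enough to knock out single-column glitches without
#'   flattening a staphyloma apex (11 columns = 0.15 mm at 0.014 mm/px).
#' @param min_contrast Minimum band intensity (on the normalized `[0,1]`
#'   scale) for a hyperreflective band to qualify; default 0.2.
#' @param axial_smooth_rows Half-width (rows) of the within-column moving
#'   average applied before band finding; default 4 rows, of the order of the
#'   RPE band thickness, which suppresses speckle-like noise without displacing
#'   a symmetric band's centroid.
#' @return A list of detector parameters for [detect_rpe_line()].
#' @export
rpe_detect_params <- function(smooth_halfwidth_cols = 5L, min_contrast = 0.2,
                              axial_smooth_rows = 4L) {
  if (min_contrast <= 0 || min_contrast >= 1)
    config_error("min_contrast must be in (0, 1)")
  list(smooth_halfwidth_cols = as.integer(smooth_halfwidth_cols),
       min_contrast = min_contrast,
       axial_smooth_rows = as.integer(axial_smooth_rows))
}

# Rolling median that ignores NAs inside the window and keeps NA where the
# center sample is missing, so gap columns stay gaps for interpolate_gaps.
roll_median_na <- function(z, halfwidth) {
  if (halfwidth <= 0) return(z)
  n <- length(z)
  out <- z
  for (i in which(!is.na(z))) {
    h <- min(halfwidth, i - 1L, n - i)   # symmetric window, shrunk at the edges
    w <- z[(i - h):(i + h)]
    out[i] <- stats::median(w, na.rm = TRUE)
  }
  out
}

#' Detect the RPE segmentation line in a B-scan
#'
#' Stand-in for the OCT device's own layer segmentation. Per column, the
#' intensity trace is smoothed axially, runs of at least two consecutive rows
#' above the contrast threshold are located, and the deepest such run is taken
#' as the RPE: anatomically, the RPE is the posterior-most strongly
#' hyperreflective band of the retina. The column's depth is the run's
#' intensity-weighted centroid (weights `intensity - threshold`, so the run's
#' edges contribute nothing and a symmetric band's centroid is its exact
#' center, giving sub-pixel accuracy). Columns with no qualifying band are
#' marked missing; the depth series is then median-filtered across columns.
#'
#' @param img A [read_bscan()] image.
#' @param params Detector parameters from [rpe_detect_params()].
#' @return A [segline] with `source = "detected"`; depths in mm
#'   (`depth_mm = centroid_row * px_v`, 0-based rows).
#' @export
detect_rpe_line <- function(img, params = rpe_detect_params()) {
  if (!inherits(img, "bscan_image"))
    validation_error("detect_rpe_line expects a bscan_image")
  px <- img$pixels
  a <- params$axial_smooth_rows
  if (a > 0) {
    k <- rep(1 / (2 * a + 1), 2 * a + 1)
    sm <- stats::filter(px, k, sides = 2)           # column-wise moving average
    sm <- matrix(as.numeric(sm), nrow(px), ncol(px))
  } else sm <- px
  thr <- params$min_contrast
  depth_rows <- vapply(seq_len(ncol(px)), function(j) {
    v <- sm[, j]
    above <- !is.na(v) & v >= thr
    if (!any(above)) return(NA_real_)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= 2L
    if (!any(keep)) return(NA_real_)
    i <- max(which(keep))                            # deepest qualifying band
    rows <- starts[i]:ends[i]
    w <- v[rows] - thr
    sum(w * (rows - 1)) / sum(w)                     # 0-based row centroid
  }, numeric(1))
  depth_rows <- roll_median_na(depth_rows, params$smooth_halfwidth_cols)
  if (mean(is.na(depth_rows)) > 0.2)
    detection_error(sprintf(
      "RPE detection failed on eye %s angle %s: %.0f%% of columns have no qualifying band",
      img$eye_id, format(img$scan_angle_deg), 100 * mean(is.na(depth_rows))))
  segline(depth_rows * img$px_v, px_h = img$px_h, eye_id = img$eye_id,
          scan_angle_deg = img$scan_angle_deg, source = "detected")
}
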