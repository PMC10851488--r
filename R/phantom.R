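#' Synthetic-eye phantom specification
#'
#' Parameters of a synthetic posterior pole with analytically known
#' curvature, used to validate every pipeline stage without clinical data.
#' The posterior wall is the inside view of a sphere of radius `rho_mm`
#' (fovea deepest), with an optional Gaussian outpouching: an isotropic 3-D
#' bump of depth amplitude `bump_A_mm` and width `bump_sigma_mm` whose apex
#' sits `bump_center_mm` lateral to the scan center at azimuth
#' `bump_azimuth_deg`. A radial scan at angle theta sees the bump at lateral
#' position `d*cos(theta - phi)` with effective amplitude reduced by
#' `exp(-(d*sin(theta - phi))^2 / (2*sigma^2))` — for a centered bump all 12
#' scans are identical; an off-center bump exercises the radial averaging
#' nontrivially. A centered bump's apex curvature is exactly
#' `1/rho + A/sigma^2`, so the target apex radius is
#' `(1/rho + A/sigma^2)^(-1)` in closed form.
#'
#' Rendering parameters place a Gaussian-profile hyperreflective band on the
#' line (`band_thickness_mm` is twice the band profile's Gaussian sigma),
#' add zero-mean Gaussian intensity noise of sd `noise_sigma`, and can store
#' the raster with the device display's 2x vertical elongation
#' (`display_stretch`) — rows duplicated and the stored axial pitch divided
#' accordingly, so the metadata always carries the true pitch of what is
#' stored.
#'
#' @param rho_mm Base sphere radius, mm; must exceed the scan half-width.
#' @param bump_A_mm Outpouching depth amplitude, mm (0 = pure sphere).
#' @param bump_sigma_mm Outpouching Gaussian width, mm.
#' @param bump_center_mm Radial offset of the bump apex from the scan
#'   center, mm.
#' @param bump_azimuth_deg Azimuth of the bump apex, degrees.
#' @param n_scans Radial scan count (default 12, evenly spaced over 180
#'   degrees).
#' @param n_cols Columns per B-scan (default 643: a 9-mm scan at 0.014
#'   mm/px).
#' @param px_h,px_v Rendering pitches, mm/pixel.
#' @param depth_offset_mm Depth of the wall at the scan edges, mm (places
#'   the line inside the raster).
#' @param display_stretch Vertical display elongation factor (default 2).
#' @param noise_sigma Additive intensity noise sd on the `[0,1]` scale.
#' @param band_thickness_mm,band_amplitude RPE band rendering parameters.
#' @param seed RNG seed fixing all stochastic output.
#' @param eye_id Identifier stamped on generated scans.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(rho_mm = 12, bump_A_mm = 0, bump_sigma_mm = 1.2,
                         bump_center_mm = 0, bump_azimuth_deg = 0,
                         n_scans = 12L, n_cols = 643L,
                         px_h = 0.014, px_v = 0.0026,
                         depth_offset_mm = 1.0, display_stretch = 2,
                         noise_sigma = 0, band_thickness_mm = 0.05,
                         band_amplitude = 0.8, seed = 1L,
                         eye_id = "phantom") {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  half_w <- (n_cols - 1) * px_h / 2
  if (!is.finite(rho_mm) || rho_mm <= half_w)
    validation_error(sprintf(
      "phantom: sphere radius %.3g mm must exceed the scan half-width %.3g mm",
      rho_mm, half_w))
  if (bump_A_mm < 0) validation_error("phantom: bump_A_mm must be >= 0")
  if (bump_A_mm > 0 && bump_sigma_mm <= 0)
    validation_error("phantom: bump_sigma_mm must be positive when a bump is present")
  if (px_h <= 0 || px_v <= 0) validation_error("phantom: pitches must be positive")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s: rho=%.4g mm%s, %d scans x %d cols\n",
              x$eye_id, x$rho_mm,
              if (x$bump_A_mm > 0)
                sprintf(", bump A=%.3g mm sigma=%.3g mm (apex radius %.3g mm)",
                        x$bump_A_mm, x$bump_sigma_mm, phantom_apex_radius(x))
              else "",
              x$n_scans, x$n_cols))
  invisible(x)
}

#' Analytic apex radius of a phantom
#'
#' For a centered bump the curvature at the apex is exactly
#' `1/rho + A/sigma^2` (the sphere's curvature plus the Gaussian's), so the
#' osculating radius there is its reciprocal; with no bump it is `rho`
#' itself. Note the three-point radius over a finite 2.8-mm chord on a
#' non-circular curve is biased above this osculating value — tolerances in
#' validation are therefore set against the three-point construction itself
#' (see the continuous-curve oracle in the tests), not against this number.
#'
#' @param spec A [phantom_spec()].
#' @return The apex osculating radius in mm.
#' @export
phantom_apex_radius <- function(spec) {
  1 / (1 / spec$rho_mm + spec$bump_A_mm / spec$bump_sigma_mm^2)
}

# Continuous wall depth z(x) for one scan: inside view of the sphere,
# deepest at the scan center, normalized to depth_offset at the edges,
# plus the scan-plane restriction of the 3-D Gaussian bump.
phantom_depth_fun <- function(spec, scan_angle_deg) {
  half_w <- (spec$n_cols - 1) * spec$px_h / 2
  rho <- spec$rho_mm
  rel <- (scan_angle_deg - spec$bump_azimuth_deg) * pi / 180
  x0 <- spec$bump_center_mm * cos(rel)
  A_eff <- if (spec$bump_A_mm > 0)
    spec$bump_A_mm *
      exp(-(spec$bump_center_mm * sin(rel))^2 / (2 * spec$bump_sigma_mm^2))
  else 0
  force(half_w); force(rho); force(x0); force(A_eff)
  function(x) {
    z <- spec$depth_offset_mm + sqrt(rho^2 - x^2) - sqrt(rho^2 - half_w^2)
    if (A_eff > 0)
      z <- z + A_eff * exp(-(x - x0)^2 / (2 * spec$bump_sigma_mm^2))
    z
  }
}

#' Generate one phantom segmentation line
#'
#' Samples the phantom wall depth at the scan's column positions
#' (`x` centered on the scan, spacing `px_h`) and returns a gap-free
#' [segline]. Deterministic: lines carry no noise (noise enters only through
#' image rendering).
#'
#' @param spec A [phantom_spec()].
#' @param scan_angle_deg Radial scan angle in degrees.
#' @return A [segline] with `source = "machine"`.
#' @export
phantom_line <- function(spec, scan_angle_deg = 0) {
  zfun <- phantom_depth_fun(spec, scan_angle_deg)
  x <- (seq_len(spec$n_cols) - 1 - (spec$n_cols - 1) / 2) * spec$px_h
  segline(zfun(x), px_h = spec$px_h, eye_id = spec$eye_id,
          scan_angle_deg = scan_angle_deg, source = "machine")
}

#' Generate a full radial scan set for one phantom eye
#'
#' @param spec A [phantom_spec()].
#' @return List of `n_scans` [segline]s at angles evenly spaced over
#'   `[0, 180)` degrees.
#' @export
phantom_eye <- function(spec) {
  angles <- seq(0, 180, length.out = spec$n_scans + 1)[seq_len(spec$n_scans)]
  lapply(angles, function(a) phantom_line(spec, a))
}

#' Render a segmentation line into a synthetic B-scan image
#'
#' Draws a Gaussian-profile bright band centered on the line (profile sigma
#' `band_thickness_mm / 2`, peak `band_amplitude`), adds zero-mean Gaussian
#' intensity noise, and clips to `[0, 1]`. With `apply_stretch = TRUE` each
#' row is duplicated `display_stretch` times and the stored axial pitch is
#' divided by the same factor, emulating the device display's vertical
#' elongation losslessly; the returned metadata always carries the true
#' pitch of the stored raster, so analysis in mm coordinates is unaffected.
#'
#' @param line A gap-free [segline].
#' @param spec A [phantom_spec()] providing the rendering parameters.
#' @param apply_stretch Store the raster with the display elongation
#'   applied?
#' @return A `bscan_image`.
#' @export
render_bscan <- function(line, spec, apply_stretch = FALSE) {
  if (anyNA(line$depth_mm))
    validation_error("render_bscan requires a gap-free line")
  band_sd <- spec$band_thickness_mm / 2
  zmax <- max(line$depth_mm) + 4 * band_sd
  n_rows <- as.integer(ceiling(zmax / spec$px_v)) + 1L
  if (min(line$depth_mm) < 4 * band_sd)
    validation_error("render_bscan: line too close to the image top for the band profile")
  row_depth <- (seq_len(n_rows) - 1) * spec$px_v
  # band intensity: outer product over (row depth - line depth)
  img <- spec$band_amplitude *
    exp(-outer(row_depth, line$depth_mm, `-`)^2 / (2 * band_sd^2))
  if (isTRUE(apply_stretch) && spec$display_stretch > 1) {
    s <- as.integer(spec$display_stretch)
    img <- img[rep(seq_len(n_rows), each = s), , drop = FALSE]
    px_v <- spec$px_v / s
  } else px_v <- spec$px_v
  if (spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    # per-angle stream so each scan of an eye gets distinct, reproducible noise
    ang <- if (is.na(line$scan_angle_deg)) 0 else line$scan_angle_deg
    set.seed((as.integer(spec$seed) + as.integer(round(ang * 100))) %% .Machine$integer.max)
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                        nrow(img), ncol(img))
  }
  img <- pmin(pmax(img, 0), 1)
  new_bscan_image(img, px_h = line$px_h, px_v = px_v,
                  scan_angle_deg = line$scan_angle_deg, eye_id = line$eye_id)
}

#' Write a rendered B-scan to a 16-bit grayscale TIFF
#'
#' @param img A `bscan_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_bscan_tiff <- function(img, path) {
  tiff::writeTIFF(img$pixels, path, bits.per.sample = 16L)
  invisible(path)
}

#' Generate a phantom cohort with ground truth
#'
#' Writes one segmentation-line file per scan per eye under
#' `out_dir/lines/`, optionally rendered TIFF images under
#' `out_dir/images/`, and a truth table `out_dir/truth.csv` with columns
#' `eye_id, rho_mm, bump_A_mm, bump_sigma_mm, apex_radius_mm,
#' expected_class`. The expected class derives from the analytic apex radius
#' against the gray-zone band expressed in radius units
#' (`[337.5/42.7, 337.5/37.5]` mm): apex radius below the band is
#' staphyloma-consistent, above is no-staphyloma-consistent, inside is
#' indeterminate.
#'
#' @param specs List of [phantom_spec()]s with distinct `eye_id`s.
#' @param out_dir Output directory (created if needed).
#' @param write_images Also render and write TIFF B-scans?
#' @param format Line-file format, `"csv"` or `"json"`.
#' @param band Gray-zone MC band used for the expected class.
#' @return Invisibly, a list with `truth` (data frame) and `line_files`.
#' @export
phantom_cohort <- function(specs, out_dir, write_images = FALSE,
                           format = c("csv", "json"), band = c(37.5, 42.7)) {
  format <- match.arg(format)
  if (inherits(specs, "phantom_spec")) specs <- list(specs)
  ids <- vapply(specs, `[[`, character(1), "eye_id")
  if (anyDuplicated(ids))
    validation_error(paste("phantom_cohort: duplicate eye_ids:",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  line_dir <- file.path(out_dir, "lines")
  dir.create(line_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_images)
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  files <- character(0)
  for (spec in specs) {
    lines <- phantom_eye(spec)
    for (ln in lines) {
      f <- file.path(line_dir, sprintf("%s_ang%06.2f.%s", ln$eye_id,
                                       ln$scan_angle_deg, format))
      write_segline(ln, f, format = format)
      files <- c(files, f)
      if (write_images)
        write_bscan_tiff(render_bscan(ln, spec),
                         file.path(out_dir, "images",
                                   sprintf("%s_ang%06.2f.tif", ln$eye_id,
                                           ln$scan_angle_deg)))
    }
  }
  apex <- vapply(specs, phantom_apex_radius, numeric(1))
  truth <- data.frame(
    eye_id = ids,
    rho_mm = vapply(specs, `[[`, numeric(1), "rho_mm"),
    bump_A_mm = vapply(specs, `[[`, numeric(1), "bump_A_mm"),
    bump_sigma_mm = vapply(specs, `[[`, numeric(1), "bump_sigma_mm"),
    apex_radius_mm = apex,
    expected_class = ifelse(apex < KERATOMETRIC_CONSTANT / band[2],
                            "staphyloma_consistent",
                     ifelse(apex > KERATOMETRIC_CONSTANT / band[1],
                            "no_staphyloma_consistent", "indeterminate")))
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(list(truth = truth, line_files = files))
}
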