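#' RPE segmentation lines
#'
#' A `segline` holds one retinal pigment epithelium (RPE) segmentation line
#' extracted from a single OCT B-scan: one depth sample per image column, in
#' physical millimetres, together with the lateral pixel pitch and scan
#' identifiers. Depth increases from the top of the image downward
#' (`depth_mm = row * px_v` for a line read off a raster); lateral position is
#' `x_mm = column * px_h` with 0-based columns. Missing columns (vessel
#' shadows, dropouts) are `NA` and must not exceed 20% of the line, the cap
#' beyond which the line is rejected rather than repaired.
#'
#' @param depth_mm Numeric vector of per-column depths in mm; `NA` marks a
#'   missing column.
#' @param px_h Lateral pixel pitch in mm/pixel (spacing of `depth_mm` samples).
#' @param eye_id Opaque eye identifier.
#' @param scan_angle_deg Nominal radial-scan angle in degrees.
#' @param source One of `"machine"` (device segmentation loaded from file),
#'   `"detected"` (this package's detector), `"corrected"` (after manual
#'   correction spans were applied).
#'
#' @return An object of class `segline` with fields `depth_mm`, `x_mm`,
#'   `n_cols`, `px_h`, `source`, `eye_id`, `scan_angle_deg`.
#' @seealso [load_segline()], [write_segline()], [interpolate_gaps()],
#'   [apply_corrections()], [curvature_profile()]
#' @export
segline <- function(depth_mm, px_h, eye_id = "unknown", scan_angle_deg = NA_real_,
                    source = c("machine", "detected", "corrected")) {
  source <- match.arg(source)
  depth_mm <- as.numeric(depth_mm)
  n <- length(depth_mm)
  obj <- structure(list(
    depth_mm = depth_mm,
    x_mm = (seq_len(n) - 1) * px_h,
    n_cols = n,
    px_h = px_h,
    source = source,
    eye_id = as.character(eye_id),
    scan_angle_deg = as.numeric(scan_angle_deg)
  ), class = "segline")
  validate_segline(obj)
  obj
}

#' @export
print.segline <- function(x, ...) {
  miss <- sum(is.na(x$depth_mm))
  cat(sprintf("<segline> eye=%s angle=%s deg, %d cols @ %.4g mm/px (%.2f mm), source=%s%s\n",
              x$eye_id, format(x$scan_angle_deg), x$n_cols, x$px_h,
              x$n_cols * x$px_h, x$source,
              if (miss > 0) sprintf(", %d missing", miss) else ""))
  invisible(x)
}

validate_segline <- function(line) {
  if (!is.numeric(line$depth_mm) || line$n_cols != length(line$depth_mm))
    validation_error("segline: depth_mm length does not match n_cols")
  if (!is.finite(line$px_h) || line$px_h <= 0)
    validation_error("segline: px_h must be a positive pitch in mm/pixel")
  bad <- !is.na(line$depth_mm) & !is.finite(line$depth_mm)
  if (any(bad))
    validation_error("segline: non-finite depths present that are not NA-marked")
  frac <- mean(is.na(line$depth_mm))
  if (frac > 0.2)
    validation_error(sprintf(
      "segline rejected: %.1f%% of columns missing exceeds the 20%% cap (eye %s, angle %s)",
      100 * frac, line$eye_id, format(line$scan_angle_deg)))
  invisible(line)
}

#' Fill gaps in a segmentation line
#'
#' Missing (`NA`) depths are filled by linear interpolation between the
#' nearest valid neighbours; leading and trailing runs are filled by
#' nearest-value extension. Lines with more than 20% missing columns are
#' rejected upstream by the `segline` validator, so the fill never fabricates
#' large stretches of geometry.
#'
#' @param line A [segline].
#' @return The line with no missing values; `n_cols`, `x_mm`, `source` and all
#'   identifiers are unchanged.
#' @export
interpolate_gaps <- function(line) {
  validate_segline(line)
  z <- line$depth_mm
  if (!anyNA(z)) return(line)
  ok <- which(!is.na(z))
  if (length(ok) < 2)
    validation_error("interpolate_gaps: fewer than 2 valid columns")
  line$depth_mm <- stats::approx(line$x_mm[ok], z[ok], xout = line$x_mm,
                                 method = "linear", rule = 2)$y
  line
}

#' Manual correction overlays
#'
#' Device segmentation occasionally fails (e.g. jumps to the choroid under a
#' staphyloma edge); corrections are expressed as replacement spans rather
#' than edited files so the original line is preserved and the intervention is
#' auditable. Spans are 0-based half-open column intervals `[col_start,
#' col_end)`, non-overlapping, each carrying exactly `col_end - col_start`
#' replacement depths in mm.
#'
#' @param spans A list of `list(col_start=, col_end=, depths_mm=)` entries.
#' @return An object of class `correction_overlay`.
#' @seealso [apply_corrections()], [load_overlay()]
#' @export
correction_overlay <- function(spans) {
  spans <- lapply(spans, function(s) {
    list(col_start = as.integer(s$col_start), col_end = as.integer(s$col_end),
         depths_mm = as.numeric(s$depths_mm))
  })
  obj <- structure(spans, class = "correction_overlay")
  for (s in spans) {
    if (s$col_end <= s$col_start)
      validation_error("correction_overlay: empty or inverted span")
    if (length(s$depths_mm) != s$col_end - s$col_start)
      validation_error("correction_overlay: replacement length must equal span length")
  }
  if (length(spans) > 1) {
    o <- order(vapply(spans, `[[`, integer(1), "col_start"))
    starts <- vapply(spans, `[[`, integer(1), "col_start")[o]
    ends <- vapply(spans, `[[`, integer(1), "col_end")[o]
    if (any(starts[-1] < ends[-length(ends)]))
      validation_error("correction_overlay: overlapping spans")
  }
  obj
}

#' Read a correction overlay from JSON
#'
#' The file is a JSON array of objects `{"col_start":, "col_end":,
#' "depths_mm": [...]}` with 0-based half-open column spans.
#'
#' @param path Path to the overlay JSON file.
#' @return A [correction_overlay].
#' @export
load_overlay <- function(path) {
  if (!file.exists(path)) format_error(paste("overlay file not found:", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!is.list(raw)) format_error("overlay JSON must be an array of span objects")
  correction_overlay(raw)
}

#' Apply manual corrections to a segmentation line
#'
#' Replaces the depths inside each overlay span, leaves every other column
#' untouched, and marks the line `source = "corrected"`. An empty overlay is
#' the identity (source unchanged).
#'
#' @param line A [segline].
#' @param overlay A [correction_overlay].
#' @return The corrected line.
#' @export
apply_corrections <- function(line, overlay) {
  validate_segline(line)
  if (!inherits(overlay, "correction_overlay"))
    overlay <- correction_overlay(overlay)
  if (length(overlay) == 0) return(line)
  for (s in overlay) {
    if (s$col_start < 0 || s$col_end > line$n_cols)
      validation_error(sprintf(
        "correction span [%d,%d) outside the line's %d columns",
        s$col_start, s$col_end, line$n_cols))
  }
  for (s in overlay)
    line$depth_mm[(s$col_start + 1):s$col_end] <- s$depths_mm
  line$source <- "corrected"
  validate_segline(line)
  line
}

#' Write a segmentation line to CSV or JSON
#'
#' CSV dialect: comment header lines `# px_h_mm=`, `# scan_angle_deg=`,
#' `# eye_id=`, `# source=`, then `col,depth_mm` rows with 0-based column
#' indices; a missing depth is an empty field. JSON dialect: an object with
#' keys `eye_id`, `scan_angle_deg`, `px_h_mm`, `source`, `depth_mm` (array,
#' `null` = missing). The JSON writer uses 17 significant digits so depths
#' round-trip bit-exactly; CSV uses 9 decimal places (sub-nanometre).
#'
#' @param line A [segline].
#' @param path Output path; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_segline <- function(line, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  validate_segline(line)
  if (format == "json") {
    obj <- list(eye_id = line$eye_id, scan_angle_deg = line$scan_angle_deg,
                px_h_mm = line$px_h, source = line$source,
                depth_mm = line$depth_mm)
    writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                                na = "null", null = "null"), path)
  } else {
    hdr <- c(sprintf("# px_h_mm=%s", fmt_double(line$px_h)),
             sprintf("# scan_angle_deg=%s", fmt_double(line$scan_angle_deg)),
             sprintf("# eye_id=%s", line$eye_id),
             sprintf("# source=%s", line$source),
             "col,depth_mm")
    rows <- sprintf("%d,%s", seq_len(line$n_cols) - 1L,
                    ifelse(is.na(line$depth_mm), "",
                           sprintf("%.9f", line$depth_mm)))
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}

parse_hdr_field <- function(lines, key) {
  pat <- paste0("^#\\s*", key, "=")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  sub(pat, "", hit[[1]])
}

#' Load a segmentation line from CSV or JSON
#'
#' Reads the dialects written by [write_segline()] (also the interchange
#' format for device-exported lines). Column spacing must be uniform: the CSV
#' `col` indices must be consecutive 0-based integers. Lines with more than
#' 20% missing depths are rejected.
#'
#' @param path Path to a `.csv` or `.json` segmentation-line file.
#' @return A [segline] with `source` as recorded in the file (default
#'   `"machine"`).
#' @export
load_segline <- function(path) {
  if (!file.exists(path)) format_error(paste("segline file not found:", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    for (k in c("px_h_mm", "depth_mm"))
      if (is.null(obj[[k]])) format_error(paste("segline JSON missing key", k))
    depth <- as.numeric(obj$depth_mm)
    return(segline(depth, px_h = obj$px_h_mm,
                   eye_id = obj$eye_id %||% "unknown",
                   scan_angle_deg = obj$scan_angle_deg %||% NA_real_,
                   source = obj$source %||% "machine"))
  }
  lines <- readLines(path, warn = FALSE)
  px_h <- parse_hdr_field(lines, "px_h_mm")
  if (is.null(px_h)) format_error("segline CSV missing '# px_h_mm=' header")
  angle <- parse_hdr_field(lines, "scan_angle_deg")
  eye <- parse_hdr_field(lines, "eye_id") %||% "unknown"
  src <- parse_hdr_field(lines, "source") %||% "machine"
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0 || !grepl("^col\\s*,\\s*depth_mm", body[[1]]))
    format_error("segline CSV missing 'col,depth_mm' header row")
  df <- utils::read.csv(text = body, colClasses = c("integer", "numeric"))
  if (nrow(df) < 2 || !identical(df$col, seq_len(nrow(df)) - 1L))
    format_error("segline CSV columns must be consecutive 0-based integers (uniform spacing)")
  segline(df$depth_mm, px_h = as.numeric(px_h), eye_id = eye,
          scan_angle_deg = if (identical(angle, "NA") || is.null(angle))
            NA_real_ else as.numeric(angle),
          source = src)
}
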