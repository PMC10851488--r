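#' The keratometric constant
#'
#' 337.5 is the conventional factor that converts a corneal radius of
#' curvature in mm into keratometric diopters; the macular curvature index
#' reuses it so a posterior-pole radius can be read on the same scale as
#' corneal keratometry (MC 40 corresponds to a 40 D cornea, both at radius
#' 8.44 mm). It is deliberately not configurable: changing it would make MC
#' values incomparable across studies.
#' @export
KERATOMETRIC_CONSTANT <- 337.5

#' Macular curvature index from the mean minimum radius
#'
#' `MC = 337.5 / R`, where `R` is the mean over an eye's radial scans of each
#' scan's minimum three-point arc radius in mm. Strictly decreasing in `R`:
#' a steeper (smaller-radius) posterior wall gives a larger index.
#'
#' @param R_mm Mean minimum radius in mm; must be positive.
#' @return The dimensionless MC index.
#' @export
compute_mc <- function(R_mm) {
  if (!is.numeric(R_mm) || any(!is.finite(R_mm)) || any(R_mm <= 0))
    validation_error("compute_mc: R must be a positive finite radius in mm")
  KERATOMETRIC_CONSTANT / R_mm
}

#' Average per-scan minimum radii into R
#'
#' Arithmetic mean of `r_min_mm` over the usable (non-flagged) scans of one
#' eye. Scans flagged all-collinear (flat lines) contribute nothing; when
#' fewer than `expected_count` usable scans remain, a warning of class
#' `mcindex_undercount_warning` is signalled rather than refusing — dropped
#' scans are a fact of clinical acquisition, and the warning keeps the
#' shortfall auditable in the result.
#'
#' @param profiles List of [curvature_profile()] objects for one eye.
#' @param expected_count Nominal scan count of the radial protocol
#'   (default 12).
#' @return `R` in mm, with attribute `n_used`.
#' @export
aggregate_R <- function(profiles, expected_count = 12L) {
  if (inherits(profiles, "curvature_profile")) profiles <- list(profiles)
  usable <- Filter(function(p) !p$flagged && is.finite(p$r_min_mm), profiles)
  if (length(usable) == 0)
    aggregation_error("aggregate_R: no usable scans (all flagged collinear or missing)")
  angles <- vapply(usable, `[[`, numeric(1), "scan_angle_deg")
  am <- angles[!is.na(angles)] %% 180
  if (anyDuplicated(round(am, 6)))
    validation_error("aggregate_R: duplicate scan angles modulo 180 degrees")
  if (length(usable) < expected_count)
    warn_mcx(sprintf("only %d of %d expected scans usable",
                     length(usable), expected_count),
             "mcindex_undercount_warning")
  R <- mean(vapply(usable, `[[`, numeric(1), "r_min_mm"))
  attr(R, "n_used") <- length(usable)
  R
}

#' Classify an MC index against the staphyloma reference
#'
#' With the gray-zone band enabled (the default, `c(37.5, 42.7)` — the
#' largest index observed without staphyloma and the smallest observed with
#' definite staphyloma), values above the band are consistent with posterior
#' staphyloma, values below are consistent with its absence, and values
#' inside are indeterminate: the cohort evidence does not support treating
#' the 40 cutoff as sharp. With `band = NULL`, strict comparison against the
#' single reference (`mc > reference` is staphyloma-consistent).
#'
#' @param mc MC index value(s).
#' @param reference Single reference cutoff (default 40, radius 8.44 mm).
#' @param band Numeric `c(low, high)` gray zone, or `NULL` to disable.
#' @return Character classification: `"staphyloma_consistent"`,
#'   `"no_staphyloma_consistent"` or `"indeterminate"`.
#' @export
classify_mc <- function(mc, reference = 40, band = c(37.5, 42.7)) {
  if (!is.null(band)) {
    if (length(band) != 2 || band[1] > band[2])
      config_error("classify_mc: band must be c(low, high) with low <= high")
    ifelse(mc > band[2], "staphyloma_consistent",
           ifelse(mc < band[1], "no_staphyloma_consistent", "indeterminate"))
  } else {
    ifelse(mc > reference, "staphyloma_consistent", "no_staphyloma_consistent")
  }
}

#' Measure one eye end to end
#'
#' Runs the full per-eye pipeline over a radial scan set: gap interpolation
#' and the sliding three-point curvature profile on every segmentation line,
#' the mean minimum radius `R`, the MC index `337.5/R`, and the reference
#' classification. Warnings raised along the way (dropped scans,
#' under-count) are collected into the result.
#'
#' @param lines List of [segline] objects, one per radial scan, sharing
#'   `eye_id` and `px_h`.
#' @param cfg A [pipeline_config()].
#' @return An object of class `mc_result`: `eye_id`, `R_mm`, `mc_index`,
#'   `classification`, `n_scans_used`, `per_scan` (data frame `angle_deg`,
#'   `r_mm`, `r_min_col`), `warnings`.
#' @export
process_eye <- function(lines, cfg = pipeline_config()) {
  if (inherits(lines, "segline")) lines <- list(lines)
  if (length(lines) == 0) validation_error("process_eye: no scans supplied")
  eyes <- unique(vapply(lines, `[[`, character(1), "eye_id"))
  if (length(eyes) != 1)
    validation_error(paste("process_eye: scans from multiple eyes:",
                           paste(eyes, collapse = ", ")))
  pitches <- unique(vapply(lines, `[[`, numeric(1), "px_h"))
  if (length(pitches) != 1)
    validation_error("process_eye: scans disagree on lateral pitch px_h")
  warnings_seen <- character(0)
  profiles <- lapply(lines, function(ln) {
    tryCatch(
      curvature_profile(interpolate_gaps(ln),
                        chord_offset_mm = cfg$chord_offset_mm,
                        margin_cols = cfg$roi_margin_cols),
      mcindex_error = function(e) {
        stop_mcx(sprintf("eye %s, angle %s: %s", ln$eye_id,
                         format(ln$scan_angle_deg), conditionMessage(e)),
                 class(e)[1])
      })
  })
  flagged <- vapply(profiles, `[[`, logical(1), "flagged")
  if (any(flagged))
    warnings_seen <- c(warnings_seen, sprintf(
      "scan at %s deg flagged all-collinear; excluded from R",
      vapply(profiles[flagged], function(p) format(p$scan_angle_deg),
             character(1))))
  R <- withCallingHandlers(
    aggregate_R(profiles, expected_count = cfg$expected_scans),
    mcindex_warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  mc <- compute_mc(as.numeric(R))
  cls <- classify_mc(mc, reference = cfg$mc_reference,
                     band = if (isTRUE(cfg$use_band)) cfg$indeterminate_band
                            else NULL)
  per_scan <- data.frame(
    angle_deg = vapply(profiles, `[[`, numeric(1), "scan_angle_deg"),
    r_mm = vapply(profiles, `[[`, numeric(1), "r_min_mm"),
    r_min_col = vapply(profiles, function(p)
      as.integer(p$r_min_col %||% NA_integer_), integer(1)))
  structure(list(eye_id = eyes, R_mm = as.numeric(R), mc_index = mc,
                 classification = cls,
                 n_scans_used = attr(R, "n_used"),
                 per_scan = per_scan, warnings = warnings_seen),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> eye %s: R = %.4f mm, MC index = %.2f -> %s (%d scans)\n",
              x$eye_id, x$R_mm, x$mc_index, x$classification, x$n_scans_used))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Write a per-eye result to JSON
#'
#' @param result An [process_eye()] result.
#' @param path Output JSON path.
#' @param config_hash Optional hash of the configuration that produced the
#'   result, embedded for provenance.
#' @return `path`, invisibly.
#' @export
write_mc_result <- function(result, path, config_hash = NULL) {
  obj <- list(eye_id = result$eye_id, R_mm = result$R_mm,
              mc_index = result$mc_index,
              classification = result$classification,
              n_scans_used = result$n_scans_used,
              per_scan = result$per_scan,
              warnings = result$warnings)
  if (!is.null(config_hash)) obj$config_hash <- config_hash
  writeLines(jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                              dataframe = "rows", na = "null"), path)
  invisible(path)
}
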