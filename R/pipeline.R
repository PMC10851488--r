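#' Pipeline configuration
#'
#' All measurement constants in one declarative object: the defaults are the
#' radial-scan construction the index is defined on (9-mm scans at 0.014
#' mm/px lateral pitch, 100-column edge margins, arc endpoints 1.4 mm to each
#' side of the evaluated column, 12 radial scans, reference MC 40 with the
#' empirical gray zone 37.5-42.7). Configs round-trip losslessly through
#' JSON via [write_config()] / [read_config()], and every results file
#' embeds the hash of the config that produced it.
#'
#' @param px_h_mm Default lateral pitch for inputs that do not carry one,
#'   mm/pixel.
#' @param chord_offset_mm Arc endpoint offset from the evaluated column, mm.
#' @param roi_margin_cols Columns excluded at each lateral edge.
#' @param mc_reference Reference MC cutoff.
#' @param indeterminate_band Gray-zone MC band `c(low, high)`.
#' @param use_band Use the band (`TRUE`) or the strict single cutoff?
#' @param expected_scans Nominal radial scan count.
#' @param detector [rpe_detect_params()] for image inputs.
#' @param seed Seed for any stochastic step (phantom generation).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(px_h_mm = 0.014, chord_offset_mm = 1.4,
                            roi_margin_cols = 100L, mc_reference = 40,
                            indeterminate_band = c(37.5, 42.7),
                            use_band = TRUE, expected_scans = 12L,
                            detector = rpe_detect_params(), seed = 1L) {
  if (length(indeterminate_band) != 2 ||
      indeterminate_band[1] > indeterminate_band[2])
    config_error("indeterminate_band must be c(low, high) with low <= high")
  if (chord_offset_mm <= 0 || px_h_mm <= 0)
    config_error("chord_offset_mm and px_h_mm must be positive")
  structure(list(px_h_mm = as.numeric(px_h_mm),
                 chord_offset_mm = as.numeric(chord_offset_mm),
                 roi_margin_cols = as.integer(roi_margin_cols),
                 mc_reference = as.numeric(mc_reference),
                 indeterminate_band = as.numeric(indeterminate_band),
                 use_band = isTRUE(use_band),
                 expected_scans = as.integer(expected_scans),
                 detector = detector, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Config JSON path.
#' @export
write_config <- function(cfg, path) {
  writeLines(jsonlite::toJSON(unclass(cfg), digits = I(17),
                              auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error(paste("config file not found:", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  det <- raw$detector %||% list()
  do.call(pipeline_config, c(
    raw[setdiff(names(raw), "detector")],
    list(detector = do.call(rpe_detect_params, det))))
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_config(cfg, tf)
  unname(tools::md5sum(tf))
}

collect_seglines <- function(input_dir) {
  files <- list.files(input_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
  files[basename(files) != "truth.csv"]
}

#' Batch measurement over a directory of segmentation-line files
#'
#' Reads every `.csv`/`.json` segmentation line under `input_dir` (a
#' `truth.csv`, if present, is ignored), applies any sibling correction
#' overlay named `<line file>.corrections.json`, groups scans by the
#' `eye_id` embedded in each file, and runs [process_eye()] per eye. Failures
#' are collected per eye rather than aborting the batch: one corrupt file
#' invalidates only the eye it belongs to (or, if unreadable enough that its
#' eye is unknown, is reported under `"<ungrouped>"`).
#'
#' Outputs under `out_dir`: `results.csv` (one row per eye), one
#' `<eye_id>.json` per measured eye, and `config.json`; all embed the config
#' hash.
#'
#' @param input_dir Directory of segmentation-line files.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `results` (list of `mc_result`), `table`
#'   (data frame), `errors` (named character vector, empty on a clean run)
#'   and `config_hash`.
#' @export
run_measure <- function(input_dir, out_dir, cfg = pipeline_config()) {
  files <- collect_seglines(input_dir)
  if (length(files) == 0)
    format_error(paste("no segmentation-line files found in", input_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  errors <- list()
  note_error <- function(key, msg) {
    errors[[key]] <<- paste(c(errors[[key]], msg), collapse = "; ")
  }
  by_eye <- list()
  for (f in files) {
    ln <- tryCatch(load_segline(f), error = function(e) e)
    if (inherits(ln, "error")) {
      note_error("<ungrouped>",
                 sprintf("%s: %s", basename(f), conditionMessage(ln)))
      next
    }
    ovf <- paste0(f, ".corrections.json")
    if (file.exists(ovf)) {
      ln <- tryCatch(apply_corrections(ln, load_overlay(ovf)),
                     error = function(e) e)
      if (inherits(ln, "error")) {
        note_error("<ungrouped>",
                   sprintf("%s: %s", basename(ovf), conditionMessage(ln)))
        next
      }
    }
    by_eye[[ln$eye_id]] <- c(by_eye[[ln$eye_id]], list(ln))
  }
  hash <- config_hash(cfg)
  results <- list()
  for (eye in names(by_eye)) {
    res <- tryCatch(process_eye(by_eye[[eye]], cfg), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[eye]] <- conditionMessage(res)
    } else {
      results[[eye]] <- res
      write_mc_result(res, file.path(out_dir, paste0(eye, ".json")),
                      config_hash = hash)
    }
  }
  tab <- if (length(results)) do.call(rbind, lapply(results, function(r)
    data.frame(eye_id = r$eye_id, R_mm = r$R_mm, mc_index = r$mc_index,
               classification = r$classification,
               n_scans_used = r$n_scans_used,
               warnings = paste(r$warnings, collapse = "; "))))
  else data.frame(eye_id = character(0), R_mm = numeric(0),
                  mc_index = numeric(0), classification = character(0),
                  n_scans_used = integer(0), warnings = character(0))
  csv <- file.path(out_dir, "results.csv")
  writeLines(sprintf("# config_hash=%s", hash), csv)
  suppressWarnings(utils::write.table(tab, csv, sep = ",", row.names = FALSE,
                                      append = TRUE, qmethod = "double"))
  write_config(cfg, file.path(out_dir, "config.json"))
  for (eye in names(errors))
    message(sprintf("run_measure: eye %s failed: %s", eye, errors[[eye]]))
  invisible(list(results = results, table = tab, errors = errors,
                 config_hash = hash))
}

#' Generate a phantom dataset from a cohort spec file
#'
#' The spec file is a JSON array of objects whose fields are
#' [phantom_spec()] arguments (each must include a distinct `eye_id`); see
#' `system.file("extdata", "demo_cohort.json", package = "mcindex")` for a
#' worked example. The cohort seed, when given, offsets each phantom's own
#' seed so re-running with a different `--seed` changes rendered noise but
#' never the truth geometry.
#'
#' @param spec_file Path to the cohort spec JSON.
#' @param out_dir Output directory.
#' @param seed Optional integer combined with each phantom's seed.
#' @param write_images Also render TIFF B-scans?
#' @return Invisibly, the [phantom_cohort()] result.
#' @export
run_phantom <- function(spec_file, out_dir, seed = NULL, write_images = FALSE) {
  if (!file.exists(spec_file))
    config_error(paste("phantom spec file not found:", spec_file))
  raw <- jsonlite::fromJSON(spec_file, simplifyDataFrame = FALSE)
  if (!is.list(raw) || length(raw) == 0)
    validation_error("phantom spec file must be a non-empty JSON array of spec objects")
  specs <- lapply(raw, function(fields) {
    bad <- setdiff(names(fields), names(formals(phantom_spec)))
    if (length(bad))
      validation_error(paste("unknown phantom spec fields:",
                             paste(bad, collapse = ", ")))
    if (!is.null(seed))
      fields$seed <- (as.integer(fields$seed %||% 1L) +
                        as.integer(seed) * 1000L) %% .Machine$integer.max
    do.call(phantom_spec, fields)
  })
  phantom_cohort(specs, out_dir, write_images = write_images)
}

#' Curvature profile of a single scan file
#'
#' Convenience wrapper: load one segmentation-line file, interpolate gaps,
#' compute the sliding three-point profile and export it as CSV.
#'
#' @param path Segmentation-line file (CSV/JSON).
#' @param out_csv Output profile CSV path, or `NULL` to skip writing.
#' @param cfg A [pipeline_config()].
#' @return The [curvature_profile()], invisibly when `out_csv` is given.
#' @export
run_profile <- function(path, out_csv = NULL, cfg = pipeline_config()) {
  prof <- curvature_profile(interpolate_gaps(load_segline(path)),
                            chord_offset_mm = cfg$chord_offset_mm,
                            margin_cols = cfg$roi_margin_cols)
  if (is.null(out_csv)) return(prof)
  write_profile_csv(prof, out_csv)
  invisible(prof)
}
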