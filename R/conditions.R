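# Structured conditions so callers (and the batch runner) can distinguish
# configuration mistakes from malformed files from genuine detection failures.

stop_mcx <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "mcindex_error")))
}

config_error     <- function(msg) stop_mcx(msg, "mcindex_config_error")
format_error     <- function(msg) stop_mcx(msg, "mcindex_format_error")
validation_error <- function(msg) stop_mcx(msg, "mcindex_validation_error")
detection_error  <- function(msg) stop_mcx(msg, "mcindex_detection_error")
aggregation_error <- function(msg) stop_mcx(msg, "mcindex_aggregation_error")

warn_mcx <- function(msg, class = "mcindex_warning") {
  warning(warningCondition(msg, class = c(class, "mcindex_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shortest decimal string that round-trips the double exactly.
fmt_double <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
}
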