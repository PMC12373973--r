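# Internal error helpers: configuration errors (bad arguments, bad config
# files) and data errors (malformed or inconsistent inputs) carry distinct
# condition classes so callers/CLI can map them to exit codes.

abort_config <- function(msg, call = NULL) {
  stop(errorCondition(msg, class = c("revsig_config_error", "revsig_error",
                                     "error", "condition")))
}

abort_data <- function(msg, call = NULL) {
  stop(errorCondition(msg, class = c("revsig_data_error", "revsig_error",
                                     "error", "condition")))
}

need_cols <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    abort_data(sprintf("%s is missing required column(s): %s",
                       what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_scalar_number <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x)
}

# Deterministic, locale-independent ordering of gene symbols.
order_radix <- function(...) order(..., method = "radix")
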