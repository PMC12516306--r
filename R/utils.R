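# Shared condition classes and logging.
#
# All package errors carry class c("dq_<kind>_error", "dq_error", "error") so
# callers (and the CLI exit-code mapping) can distinguish configuration,
# validation, parse, I/O, contract and runtime failures.

dq_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "dq_error"), call = call))
}

dq_config_error     <- function(msg) dq_stop(msg, "dq_config_error")
dq_validation_error <- function(msg) dq_stop(msg, "dq_validation_error")
dq_parse_error      <- function(msg) dq_stop(msg, "dq_parse_error")
dq_io_error         <- function(msg) dq_stop(msg, "dq_io_error")
dq_contract_error   <- function(msg) dq_stop(msg, "dq_contract_error")
dq_runtime_error    <- function(msg) dq_stop(msg, "dq_runtime_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Emit a pipeline log line
#'
#' Writes `LEVEL | stage | message` to standard error. Logging is suppressed
#' when `options(dotquilt.quiet = TRUE)` is set (the test suite sets it).
#'
#' @param level one of "INFO", "WARN", "ERROR".
#' @param stage short stage tag, e.g. "align" or "render".
#' @param msg message text.
#' @return invisibly, the formatted line.
#' @keywords internal
dq_log <- function(level, stage, msg) {
  line <- sprintf("%s | %s | %s", level, stage, msg)
  if (!isTRUE(getOption("dotquilt.quiet", FALSE))) {
    message(line)
  }
  invisible(line)
}

# Normalize any R color spec to "#RRGGBB" (alpha dropped); errors on unknown.
normalize_color <- function(x, what = "color") {
  rgbm <- tryCatch(grDevices::col2rgb(x), error = function(e) NULL)
  if (is.null(rgbm)) {
    dq_config_error(sprintf("unknown %s: '%s'", what, x))
  }
  grDevices::rgb(rgbm[1, ], rgbm[2, ], rgbm[3, ], maxColorValue = 255)
}

# Filesystem-safe token for use in cache file names.
sanitize_id <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

pair_name <- function(target_id, query_id) {
  paste0(sanitize_id(target_id), "__", sanitize_id(query_id))
}
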