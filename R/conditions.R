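# Classed error conditions so callers (and tests) can distinguish malformed
# files, invariant violations, and bad pipeline wiring.

abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "convexpr_error"), call = call))
}

#' @noRd
abort_format <- function(msg) abort(msg, "convexpr_format_error")

#' @noRd
abort_validation <- function(msg) abort(msg, "convexpr_validation_error")

#' @noRd
abort_config <- function(msg) abort(msg, "convexpr_config_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
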