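# Structured condition classes so the pipeline runner (and its shell wrapper)
# can map error families onto distinct exit codes.

stop_invalid <- function(msg, ...) {
  rlang::abort(msg, class = c("codelistr_invalid_error", "codelistr_error"), ...)
}

stop_format <- function(msg, ...) {
  rlang::abort(msg, class = c("codelistr_format_error", "codelistr_error"), ...)
}

stop_config <- function(msg, ...) {
  rlang::abort(msg, class = c("codelistr_config_error", "codelistr_error"), ...)
}

stop_dependency <- function(msg, ...) {
  rlang::abort(msg, class = c("codelistr_dependency_error", "codelistr_error"), ...)
}

stop_reconciliation <- function(msg, ...) {
  rlang::abort(msg, class = c("codelistr_reconciliation_error", "codelistr_error"), ...)
}

#' Exit code associated with a codelistr error family
#'
#' Used by the command-line wrapper to translate structured conditions into
#' shell exit statuses: format errors return 2, configuration errors 3,
#' dependency errors 4, reconciliation errors 5, anything else 1.
#'
#' @param cnd A condition object.
#' @return An integer exit code.
#' @export
error_exit_code <- function(cnd) {
  if (inherits(cnd, "codelistr_format_error")) return(2L)
  if (inherits(cnd, "codelistr_config_error")) return(3L)
  if (inherits(cnd, "codelistr_dependency_error")) return(4L)
  if (inherits(cnd, "codelistr_reconciliation_error")) return(5L)
  1L
}
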