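# Structured conditions. All package errors inherit "lfaquant_error";
# invalid-test conditions (e.g. control line absent) get their own class so
# batch drivers can record them without aborting.

lfa_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "lfaquant_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_input <- function(message) lfa_abort(message, "lfa_input_error")

abort_config <- function(message) lfa_abort(message, "lfa_config_error")

abort_fit <- function(message) lfa_abort(message, "lfa_fit_error")

#' @rdname analyze_strip
#' @param message error message.
#' @param stage pipeline stage name attached to invalid-test conditions.
#' @export
abort_invalid_test <- function(message, stage = NULL) {
  if (!is.null(stage)) message <- sprintf("[%s] %s", stage, message)
  lfa_abort(message, "lfa_invalid_test")
}

#' @rdname analyze_strip
#' @param expr expression to evaluate.
#' @export
is_invalid_test <- function(expr) {
  tryCatch({ force(expr); FALSE }, lfa_invalid_test = function(e) TRUE)
}
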