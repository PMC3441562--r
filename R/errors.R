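# DAS error taxonomy. Command-layer code signals these by name; the HTTP
# front end owns the wire mapping (status code + X-DAS-Status header).

DAS_ERROR_NAMES <- c("BAD_COMMAND", "BAD_DATA_SOURCE", "BAD_COMMAND_ARGS",
                     "BAD_REFERENCE_OBJECT", "BAD_STYLESHEET", "SERVER_ERROR")

#' Signal a DAS protocol error
#'
#' @param name One of the taxonomy names: `BAD_COMMAND`, `BAD_DATA_SOURCE`,
#'   `BAD_COMMAND_ARGS`, `BAD_REFERENCE_OBJECT`, `BAD_STYLESHEET`,
#'   `SERVER_ERROR`.
#' @param message Human-readable detail.
#' @export
das_error <- function(name, message) {
  name <- match.arg(name, DAS_ERROR_NAMES)
  stop(structure(
    class = c(paste0("das_error_", name), "das_error", "error", "condition"),
    list(message = message, call = NULL, das_status = name)))
}

#' @rdname das_error
#' @param x Object to test.
#' @export
is_das_error <- function(x) inherits(x, "das_error")

#' @rdname das_error
#' @param cond A condition caught from DAS code.
#' @export
das_error_name <- function(cond) {
  if (is_das_error(cond)) cond$das_status else "SERVER_ERROR"
}
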