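#' @keywords internal
#' @noRd
abort_input <- function(msg, ...) {
  stop(structure(
    class = c("denshot_input_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @keywords internal
#' @noRd
abort_solver <- function(msg, ...) {
  stop(structure(
    class = c("denshot_solver_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
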