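#' @keywords internal
abort_mnar <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mnarsens_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @keywords internal
check_number <- function(x, name, lower = -Inf, upper = Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && (allow_inf || is.finite(x))
  if (!ok || x < lower || x > upper) {
    abort_mnar(
      sprintf("`%s` must be a single number in [%s, %s], got %s",
              name, format(lower), format(upper),
              paste(format(x), collapse = ", ")),
      "mnarsens_invalid_parameter"
    )
  }
  invisible(x)
}
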