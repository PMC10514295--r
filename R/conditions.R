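# Classed conditions so callers can distinguish failure modes
# programmatically (tryCatch on the subclass) instead of matching messages.

ec_stop <- function(subclass, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(subclass, "enzchar_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

ec_warn <- function(subclass, message, ...) {
  warning(structure(
    class = c(subclass, "enzchar_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stopifnot_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    ec_stop("domain_error", sprintf("`%s` must be finite numeric", name))
  }
  if (positive && any(x <= 0)) {
    ec_stop("domain_error", sprintf("`%s` must be > 0", name))
  }
  if (nonnegative && any(x < 0)) {
    ec_stop("domain_error", sprintf("`%s` must be >= 0", name))
  }
  invisible(x)
}
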