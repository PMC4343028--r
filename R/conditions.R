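# Classed conditions so callers can distinguish failure modes programmatically.

abort_cometcal <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "cometcal_error"), call = call))
}

warn_cometcal <- function(message, class) {
  warning(warningCondition(message, class = c(class, "cometcal_warning")))
}

# scalar checks used across constructors
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is_number(x)) {
    abort_cometcal(sprintf("`%s` must be a single finite number", name),
                   "cometcal_parameter_error")
  }
  if (positive && x <= 0) {
    abort_cometcal(sprintf("`%s` must be > 0", name), "cometcal_parameter_error")
  }
  if (nonneg && x < 0) {
    abort_cometcal(sprintf("`%s` must be >= 0", name), "cometcal_parameter_error")
  }
  invisible(x)
}
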