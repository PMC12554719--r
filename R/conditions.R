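# Classed conditions used across the package. Every user-facing failure mode
# carries a stable class so callers (and the batch drivers) can branch on it.

abort_ansflow <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ansflow_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

stop_parameter  <- function(msg) abort_ansflow(msg, "ansflow_parameter_error")
stop_data       <- function(msg) abort_ansflow(msg, "ansflow_data_error")
stop_degenerate <- function(msg) abort_ansflow(msg, "ansflow_degenerate_error")
stop_quality    <- function(msg) abort_ansflow(msg, "ansflow_quality_error")
stop_size       <- function(msg) abort_ansflow(msg, "ansflow_size_error")
stop_band       <- function(msg) abort_ansflow(msg, "ansflow_band_error")
stop_format     <- function(msg) abort_ansflow(msg, "ansflow_format_error")
stop_estimator  <- function(msg) abort_ansflow(msg, "ansflow_estimator_error")
stop_input      <- function(msg) abort_ansflow(msg, "ansflow_input_error")

# scalar checks -------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_parameter(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_parameter(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s",
                           name, x,
                           if (strict_lower) "(" else "[", lower, upper,
                           if (strict_upper) ")" else "]"))
  x
}

check_band <- function(band, name = "band") {
  if (!is.numeric(band) || length(band) != 2L || any(!is.finite(band)))
    stop_parameter(sprintf("`%s` must be two finite numbers", name))
  if (band[1] > band[2])
    stop_parameter(sprintf("`%s` must be ordered (lo <= hi)", name))
  as.numeric(band)
}
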