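#' Signal a classed ocor error
#'
#' All user-facing failures in the package raise conditions subclassing
#' `ocor_error`, so callers can distinguish e.g. a missing timepoint from an
#' infeasible session without parsing messages.
#'
#' @param class character; condition subclass, e.g. "ocor_missing_timepoint".
#' @param message human-readable message.
#' @param ... fields attached to the condition object.
#' @keywords internal
ocor_abort <- function(class, message, ...) {
  stop(structure(
    class = c(class, "ocor_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# condition subclasses used across the package:
#   ocor_missing_data       no baseline sample
#   ocor_missing_timepoint  no sample within tolerance of a requested time
#   ocor_domain_error       argument outside its physical domain
#   ocor_invalid_rise       delta COHb <= 0 at compute time
#   ocor_infeasible_session losses + residual exceed the administered dose
#   ocor_config_error       inconsistent configuration
#   ocor_inconsistent       internally inconsistent derived quantities
#   ocor_io_error           file/schema problems on read
#   ocor_dose_error         simulated dose infeasible (regenerate)
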