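# Classed conditions so callers can distinguish I/O, integrity, format,
# configuration, state and domain failures programmatically.

trialops_error <- function(class, message, data = NULL) {
  stop(structure(
    class = c(class, "trialops_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  ))
}

abort_io        <- function(msg, data = NULL) trialops_error("trialops_io_error", msg, data)
abort_integrity <- function(msg, data = NULL) trialops_error("trialops_integrity_error", msg, data)
abort_format    <- function(msg, data = NULL) trialops_error("trialops_format_error", msg, data)
abort_config    <- function(msg, data = NULL) trialops_error("trialops_config_error", msg, data)
abort_state     <- function(msg, data = NULL) trialops_error("trialops_state_error", msg, data)
abort_domain    <- function(msg, data = NULL) trialops_error("trialops_domain_error", msg, data)
abort_precondition <- function(msg, data = NULL) trialops_error("trialops_precondition_error", msg, data)
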