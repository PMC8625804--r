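# Classed conditions so callers (and tests) can distinguish failure modes
# without parsing messages.

stop_hrm <- function(type, msg, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("hrm_", type), "hrm_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = call)
  )
  stop(cond)
}

warn_hrm <- function(type, msg, ...) {
  cond <- structure(
    class = c(paste0("hrm_", type), "hrm_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  )
  warning(cond)
}
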