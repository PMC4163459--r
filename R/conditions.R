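# Structured error classes so the CLI can map failures to distinct exit
# codes: format errors (malformed input files), validation errors (well-formed
# input violating a domain invariant), configuration errors.

drimm_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "drimm_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_format <- function(msg) drimm_error(msg, "drimm_format_error")
stop_validation <- function(msg) drimm_error(msg, "drimm_validation_error")
stop_config <- function(msg) drimm_error(msg, "drimm_config_error")
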