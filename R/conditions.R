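# Structured error conditions so callers (and the CLI) can map failures to
# exit codes without string matching.

abort_domain <- function(msg) {
  stop(errorCondition(msg, class = c("maxentseg_domain_error", "maxentseg_error")))
}

abort_format <- function(msg) {
  stop(errorCondition(msg, class = c("maxentseg_format_error", "maxentseg_error")))
}

abort_feasibility <- function(msg) {
  stop(errorCondition(msg, class = c("maxentseg_feasibility_error", "maxentseg_error")))
}

abort_resource <- function(msg) {
  stop(errorCondition(msg, class = c("maxentseg_resource_error", "maxentseg_error")))
}
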