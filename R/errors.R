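# Structured error conditions. Each user-facing failure carries a class so
# the command-line wrapper can map it to a distinct exit status:
#   input error -> 2, format error -> 3, configuration error -> 4.

pf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pullfan_error"), call = call))
}

pf_stop_input <- function(msg) pf_stop(msg, "pullfan_input_error")
pf_stop_format <- function(msg) pf_stop(msg, "pullfan_format_error")
pf_stop_config <- function(msg) pf_stop(msg, "pullfan_config_error")
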