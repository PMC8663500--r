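# Structured conditions so callers (and the command-line wrapper) can
# distinguish bad input from numerical failure.

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("rehabElo_input_error", "rehabElo_error", "error")))
}

stop_numeric <- function(fmt, ..., diagnostics = NULL) {
  stop(errorCondition(sprintf(fmt, ...),
                      diagnostics = diagnostics,
                      class = c("rehabElo_numeric_error", "rehabElo_error", "error")))
}
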