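# Classified conditions so the CLI can map failures to exit codes:
# config errors (bad parameters), input errors (bad files/identifiers),
# convergence errors (walk did not reach the fixed point).

.configError <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("rwrscreen_config_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

.inputError <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("rwrscreen_input_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

.convergenceError <- function(msg, residual, call = sys.call(-1)) {
  stop(structure(
    class = c("rwrscreen_convergence_error", "error", "condition"),
    list(message = msg, call = call, residual = residual)
  ))
}
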