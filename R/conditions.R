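# Classed conditions so the CLI can map failures to distinct exit codes.

stop_validation <- function(msg) {
  stop(structure(class = c("bloodEIS_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_convergence <- function(msg) {
  stop(structure(class = c("bloodEIS_convergence_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_io <- function(msg) {
  stop(structure(class = c("bloodEIS_io_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
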