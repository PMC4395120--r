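# Classed conditions so callers and tests can distinguish failure modes.

abort <- function(message, class) {
  stop(structure(
    class = c(class, "archepsy_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_invalid_argument <- function(msg) abort(msg, "archepsy_invalid_argument")
stop_insufficient_signal <- function(msg) abort(msg, "archepsy_insufficient_signal")
stop_insufficient_data <- function(msg) abort(msg, "archepsy_insufficient_data")
stop_invalid_design <- function(msg) abort(msg, "archepsy_invalid_design")
stop_degenerate_variance <- function(msg) abort(msg, "archepsy_degenerate_variance")
stop_missing_channel <- function(msg) abort(msg, "archepsy_missing_channel")
stop_config <- function(msg) abort(msg, "archepsy_config_error")

warn_classed <- function(message, class) {
  warning(structure(
    class = c(class, "archepsy_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
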