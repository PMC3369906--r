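# Condition constructors used across the package. Two error families map onto
# the command-line exit codes: data errors (malformed or degenerate inputs,
# exit 1) and config errors (invalid parameters, exit 2).

ps_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "painscreen_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_config <- function(msg) ps_stop(msg, "painscreen_config_error")
stop_data <- function(msg) ps_stop(msg, "painscreen_data_error")

ps_warn <- function(msg, class = "painscreen_warning") {
  warning(warningCondition(msg, class = class))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
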