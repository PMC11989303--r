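#' @keywords internal
stop_asthmanet <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "asthmanet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

stop_validation <- function(msg, ...) {
  stop_asthmanet(msg, "asthmanet_validation_error", ...)
}

stop_config <- function(field, msg) {
  stop_asthmanet(sprintf("invalid generator configuration: field '%s' %s", field, msg),
                 "asthmanet_config_error", field = field)
}
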