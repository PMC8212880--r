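# Classed error conditions so callers (and tests) can distinguish a malformed
# input file from a bad parameter or a degenerate dataset.

graftnet_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "graftnet_error")))
}

stop_format <- function(msg) graftnet_stop(msg, "graftnet_format_error")
stop_param  <- function(msg) graftnet_stop(msg, "graftnet_parameter_error")
stop_data   <- function(msg) graftnet_stop(msg, "graftnet_data_error")
stop_config <- function(msg) graftnet_stop(msg, "graftnet_config_error")
stop_io     <- function(msg) graftnet_stop(msg, "graftnet_io_error")
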