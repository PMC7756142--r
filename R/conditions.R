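# Classed conditions so callers (and the CLI) can map failures to exit codes.

sr_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "sharedreach_error", "error")))
}

stop_invalid <- function(msg) sr_stop(msg, "sharedreach_invalid_argument")
stop_alignment <- function(msg) sr_stop(msg, "sharedreach_alignment_error")
stop_no_touch <- function(msg) sr_stop(msg, "sharedreach_no_touch_error")
stop_degenerate <- function(msg) sr_stop(msg, "sharedreach_degenerate_sample")
stop_incomplete <- function(msg) sr_stop(msg, "sharedreach_incomplete_design")
stop_parse <- function(msg) sr_stop(msg, "sharedreach_parse_error")
stop_no_data <- function(msg) sr_stop(msg, "sharedreach_no_data")
stop_undefined_rt <- function(msg) sr_stop(msg, "sharedreach_undefined_rt")
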