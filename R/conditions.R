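# Classed conditions so callers can distinguish bad user input, broken
# federation protocol state, and statistically undefined results.

fs_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "fedsurv_error")))
}

stop_invalid <- function(...) fs_stop(paste0(...), "fedsurv_invalid_input")
stop_protocol <- function(...) fs_stop(paste0(...), "fedsurv_protocol_error")
stop_undefined <- function(...) fs_stop(paste0(...), "fedsurv_undefined_result")

`%||%` <- function(a, b) if (is.null(a)) b else a
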