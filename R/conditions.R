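# Classed conditions so callers can branch on failure mode rather than
# matching message text. All errors inherit from "gaitsym_error".

stop_gaitsym <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gaitsym_error")))
}

warn_gaitsym <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "gaitsym_warning")))
}
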