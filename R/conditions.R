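## Structured error conditions. Every error raised by the package carries
## class c("mrsbids_<What>", "mrsbids_error", "error", "condition") so callers
## (and tests) can dispatch on the precise failure class.

mrsStop <- function(what, message, ...) {
  stop(errorCondition(
    sprintf(message, ...),
    class = c(paste0("mrsbids_", what), "mrsbids_error")
  ))
}

mrsWarn <- function(what, message, ...) {
  warning(warningCondition(
    sprintf(message, ...),
    class = c(paste0("mrsbids_", what), "mrsbids_warning")
  ))
}
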