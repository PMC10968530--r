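# Classed conditions so callers can distinguish failure modes programmatically.
# Every error raised by the package carries class "iwireError" plus a
# specific subclass (e.g. "iwireNoBeatError").

iwireStop <- function(subclass, msg, ...) {
  stop(errorCondition(msg, ..., class = c(subclass, "iwireError", "error")))
}

iwireParamStop <- function(msg, ...) iwireStop("iwireParameterError", msg, ...)
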