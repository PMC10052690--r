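# Classed conditions so callers can distinguish degenerate inputs from misuse.
# Classes in use: usage_error, degenerate_object_error, codec_error,
# metric_error, spec_error, optim_error.
abort_bs <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "beziershape_error")))
}
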