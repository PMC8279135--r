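# Structured error conditions so callers can distinguish "the metric is
# mathematically undefined on this input" from ordinary misuse.

undefined_metric_error <- function(metric, reason) {
  stop(errorCondition(
    sprintf("metric '%s' is undefined: %s", metric, reason),
    metric = metric, reason = reason,
    class = c("regeval_undefined_metric", "regeval_error")
  ))
}

domain_error <- function(fmt, ...) {
  stop(errorCondition(
    sprintf(fmt, ...),
    class = c("regeval_domain_error", "regeval_error")
  ))
}
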