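# Structured conditions. Every error signalled by this package carries class
# c("vaekb_<kind>", "vaekb_error", "error", "condition") so callers can branch
# on the kind without string-matching messages.

vaekb_abort <- function(kind, msg, ...) {
  cond <- structure(
    class = c(paste0("vaekb_", kind), "vaekb_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

vaekb_warn <- function(kind, msg, ...) {
  cond <- structure(
    class = c(paste0("vaekb_", kind), "vaekb_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  warning(cond)
}
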