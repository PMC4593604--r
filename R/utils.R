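# Internal helpers shared across modules.

# Classed condition so callers can distinguish error families programmatically.
vmr_abort <- function(message, class) {
  stop(structure(
    class = c(class, "vmr_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

vmr_warn <- function(message, class = "vmr_warning") {
  warning(structure(
    class = c(class, "vmr_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

clamp01 <- function(x) pmin(1, pmax(0, x))

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= 1
}

# Stable per-animal seed derivation: one root seed, counter-based substreams,
# kept inside 32-bit integer range. Adding animals never perturbs earlier ones.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
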