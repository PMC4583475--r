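#' @keywords internal
"_PACKAGE"

# Run code under a local RNG state derived from `seed`; the caller's RNG
# stream is untouched. All stochastic operations in the package funnel
# through this so that (inputs, seed) fully determine outputs.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a child seed for a named sub-stream. Keeps hierarchical splitting
# reproducible without consuming the parent stream. Result < 2^31.
child_seed <- function(seed, label) {
  u <- utf8ToInt(as.character(label))
  h <- 0
  for (c in u) h <- (h * 131 + c) %% 30011111
  as.integer((as.numeric(seed) * 7919 + h * 67) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}
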