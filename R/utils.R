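# Shared internals: seeding, quantile summaries, small validators.

# Seed the global RNG and return thin wrappers.  Keeping the wrappers (rather
# than calling set.seed at call sites) centralizes the integer-range guard.
local_rng <- function(seed) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  set.seed(as.integer(abs(as.numeric(seed)) %% 2147483647L))
  list(runif = stats::runif, rnorm = stats::rnorm, rpois = stats::rpois)
}

# Deterministic substream seed from a master seed and a stream label, kept
# below 2^31 so it is always a valid R integer seed.  Adding individuals to a
# design does not perturb draws of other streams because each stream is
# seeded independently.
substream_seed <- function(master, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1013904223
  as.integer((as.numeric(master) * 2654435761 + h) %% 2147483647)
}

# Equal-tailed credible interval plus median from a draw vector.
ci_summary <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(x, c(a, 0.5, 1 - a), names = FALSE, type = 7)
  list(ci_low = q[1], median = q[2], ci_high = q[3])
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number")
  invisible(x)
}
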