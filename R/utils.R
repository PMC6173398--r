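# internal helpers shared across modules

# counter-based sub-seed derivation: stratum i always gets the same stream
# for a given master seed, independent of how many strata precede it.
# Park-Miller style mixing keeps everything inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  x <- (abs(seed) %% m)
  x <- (x * 48271 + index * 2654435) %% m
  as.integer(x %% 2147483647L)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

assert_positive_se <- function(se, what = "se") {
  if (any(!is.finite(se)) || any(se <= 0)) {
    abort(sprintf("all %s values must be finite and > 0", what))
  }
  invisible(se)
}

# two-sided normal p-value from an estimate and its SE
wald_p <- function(beta, se) 2 * pnorm(-abs(beta / se))
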