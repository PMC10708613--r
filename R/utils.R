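#' @keywords internal
"_PACKAGE"

## Seed handling: every stochastic entry point takes an explicit seed and
## restores the caller's RNG state afterwards, so library code never
## perturbs a user's session RNG.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Deterministic per-case / per-module seed derivation, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483563) + 1L
}

## Truncated normal init (+/- 2 sd), the ViT convention.
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2)
  hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Largest divisor of C that is <= limit; used to pick group-norm groups for
## narrow reduced-width channels.
norm_groups <- function(channels, limit = 32L) {
  g <- min(limit, channels)
  while (channels %% g != 0L) g <- g - 1L
  g
}
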