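#' Derive a stage seed from a master seed
#'
#' All stochastic operations take one explicit integer seed. Multi-stage
#' workflows fan a single master seed out to per-stage seeds with this
#' counter scheme, so every stage is independently reproducible and the
#' derived seed is recorded in run manifests. The map is a fixed affine
#' hash modulo the largest 32-bit prime, guaranteeing a valid R seed.
#'
#' @param seed master seed (single integer-valued number).
#' @param counter non-negative stage counter.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  assert_that(is.numeric(counter) && length(counter) == 1 && counter >= 0,
              "counter must be a single non-negative number")
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(seed) %% m)
  # two rounds of a multiplicative congruential step, offset by the counter
  s <- (s * 48271 + counter * 16807 + 1) %% m
  s <- (s * 48271 + 12345) %% m
  as.integer(s %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
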