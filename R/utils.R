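#' Derive a reproducible child seed
#'
#' Experiment functions draw each Monte-Carlo replicate under its own seed so
#' that curves over a richness grid are reproducible and extensible: adding a
#' new `S` never changes the replicates already drawn for another `S`.
#' The child seed is a deterministic function of (base seed, S, replicate
#' index), kept strictly below 2^31 - 1.
#'
#' @param seed base integer seed.
#' @param S species richness the replicate belongs to.
#' @param k replicate index (0 is reserved for per-configuration setup such
#'   as the Monte-Carlo mean interaction matrix).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, S, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  s <- (abs(seed) %% m)
  # two rounds of multiplicative mixing, exact in double precision
  s <- (s * 48271 + S * 16807) %% m
  s <- (s * 69621 + k + 1) %% m
  as.integer(s)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return named numeric vector with elements `lower` and `upper`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Normal-approximation (Wald) confidence interval for a proportion
#'
#' Provided alongside [wilson_ci()] because published feasibility curves
#' typically show plain binomial intervals; the Wilson interval is the
#' package default since it behaves sensibly at estimates of 0 or 1.
#'
#' @inheritParams wilson_ci
#' @return named numeric vector with elements `lower` and `upper`.
#' @export
wald_ci <- function(k, n, level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}

# run `expr` under `seed` without disturbing the caller's RNG state;
# seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_param <- function(...) stop(..., call. = FALSE)
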