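#' @title Stability criteria and closed-form feasibility theory
#' @name lv_stability
NULL

#' Classify the interaction-strength regime
#'
#' The scaling exponent partitions into strong (`0 <= delta < 1/2`),
#' moderate (`delta = 1/2`) and weak (`1/2 < delta <= 1`) interactions.
#' The comparison at 1/2 is exact on the entered value (configuration files
#' carry `delta` as a decimal string for this reason).
#'
#' @param delta scaling exponent in \[0, 1\].
#' @return `"strong"`, `"moderate"` or `"weak"`.
#' @export
classify_regime <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta > 1)
    stop_param("`delta` must lie in [0, 1]")
  if (delta < 0.5) "strong" else if (delta == 0.5) "moderate" else "weak"
}

#' May's stability condition
#'
#' For large unstructured communities the random-matrix surrogate of the
#' Jacobian has all eigenvalues in the left half-plane when
#' `sigma (C S)^-delta sqrt(C S) < |theta|`. At `delta = 1/2` the
#' criterion collapses to `sigma < |theta|`, independent of `S` and `C`;
#' at `delta = 0` it is violated for any fixed `sigma` once `S` grows.
#'
#' @param sigma interaction strength standard deviation (> 0).
#' @param C,S community parameters (`C * S > 0`).
#' @param delta scaling exponent.
#' @param theta intraspecific competition coefficient (negative).
#' @return `TRUE` when the criterion is satisfied.
#' @export
may_stability_condition <- function(sigma, C, S, delta, theta = -1) {
  stopifnot(sigma > 0, C * S > 0)
  if (theta >= 0) stop_param("`theta` must be negative")
  sigma * normalization_factor(C, S, delta) * sqrt(C * S) < abs(theta)
}

#' Spectral stability of a community matrix
#'
#' Computes the eigenvalue spectrum with a general nonsymmetric solver.
#' The equilibrium is linearly stable iff the largest real part is
#' strictly negative; a leading real part of exactly zero is reported
#' unstable (no tolerance band).
#'
#' @param J a square numeric matrix.
#' @return list with `stable` (flag), `leading` (largest real part) and
#'   `eigenvalues` (complex vector).
#' @export
spectral_stability <- function(J) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J))
  if (!all(is.finite(J))) stop_param("`J` contains non-finite entries")
  ev <- eigen(J, only.values = TRUE)$values
  leading <- max(Re(ev))
  list(stable = leading < 0, leading = leading, eigenvalues = ev)
}

#' Closed-form feasibility probability under moderate interactions
#'
#' For May's unstructured model at `delta = 1/2` with the mean structural
#' growth-rate vector and `0 < sigma < |theta|`, the equilibrium abundances
#' are asymptotically i.i.d. Gaussian and the feasibility probability is
#' approximately `Phi(sqrt((theta^2 - sigma^2) / sigma^2))^S`, a power-law
#' decay to zero in `S`. At `sigma >= |theta|` the system is structurally
#' unstable and the formula does not apply.
#'
#' @param S species richness.
#' @param sigma interaction strength standard deviation (0 < sigma < |theta|).
#' @param theta intraspecific competition coefficient (negative).
#' @return the analytic feasibility probability.
#' @examples
#' analytic_feasibility_probability(25, sigma = 0.4, theta = -1) # ~0.759
#' @export
analytic_feasibility_probability <- function(S, sigma = 0.4, theta = -1) {
  if (theta >= 0) stop_param("`theta` must be negative")
  if (!is.numeric(sigma) || any(sigma <= 0) || any(sigma >= abs(theta)))
    stop_param("requires 0 < sigma < |theta| (otherwise the system is ",
               "structurally unstable)")
  stats::pnorm(sqrt((theta^2 - sigma^2) / sigma^2))^S
}

#' Asymptotic abundance moments under moderate interactions
#'
#' With i.i.d. growth rates of mean `r_bar` and variance `sigma_r_sq`, and
#' `sigma < |theta|`, each equilibrium abundance is asymptotically
#' `N(mu_star, sigma_star_sq)` with `mu_star = -r_bar / theta` and
#' `sigma_star_sq = sigma_r^2 / theta^2 +
#' r2 sigma^2 / (theta^2 (theta^2 - sigma^2))` where
#' `r2 = sigma_r^2 + r_bar^2` is the second moment of the growth rates.
#'
#' @param r_bar mean intrinsic growth rate.
#' @param sigma_r_sq variance of the intrinsic growth rates.
#' @param sigma interaction strength standard deviation.
#' @param theta intraspecific competition coefficient (negative).
#' @return list with `mu_star` and `sigma_star_sq`.
#' @export
moderate_regime_moments <- function(r_bar, sigma_r_sq, sigma, theta = -1) {
  if (theta >= 0) stop_param("`theta` must be negative")
  if (sigma < 0 || sigma >= abs(theta))
    stop_param("requires 0 <= sigma < |theta|")
  if (sigma_r_sq < 0) stop_param("`sigma_r_sq` must be non-negative")
  r2 <- sigma_r_sq + r_bar^2
  list(
    mu_star = -r_bar / theta,
    sigma_star_sq = sigma_r_sq / theta^2 +
      r2 * sigma^2 / (theta^2 * (theta^2 - sigma^2))
  )
}

#' Weak-interaction feasibility limit
#'
#' Under weak interactions (`1/2 < delta <= 1`) in unstructured webs the
#' equilibrium converges to a deterministic vector, so the feasibility
#' probability converges to 1 when `r_i > r_bar mu_A / (mu_A + theta)` for
#' every species, and to 0 otherwise. Here `mu_A` is the mean interaction
#' strength between interacting species and `r_bar` the sample mean of the
#' growth rates. In May's framework (`mu_A = 0`) the condition is simply
#' that all growth rates are positive; the mean structural vector always
#' satisfies it.
#'
#' @param r growth-rate vector.
#' @param mu_A mean interaction strength (see [mean_interaction_strength()]).
#' @param theta intraspecific competition coefficient (negative).
#' @return the predicted limit, 1 or 0.
#' @export
weak_regime_limit <- function(r, mu_A, theta = -1) {
  if (theta >= 0) stop_param("`theta` must be negative")
  if (mu_A + theta == 0)
    stop_param("`mu_A + theta` must be nonzero")
  threshold <- mean(r) * mu_A / (mu_A + theta)
  if (min(r) > threshold) 1 else 0
}

#' Tabulate the analytic feasibility curve
#'
#' Convenience wrapper producing a tidy table `S, p_s_analytic` for export.
#'
#' @param S_values vector of species richness values.
#' @inheritParams analytic_feasibility_probability
#' @return a data frame.
#' @export
analytic_feasibility_curve <- function(S_values, sigma = 0.4, theta = -1) {
  data.frame(
    S = S_values,
    p_s_analytic = vapply(S_values, analytic_feasibility_probability,
                          numeric(1), sigma = sigma, theta = theta)
  )
}
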