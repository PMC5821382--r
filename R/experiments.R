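#' @title Monte-Carlo feasibility experiments
#' @description The engine that estimates the feasibility probability
#'   `P_S = P(x*_i > 0 for all i)` by repeatedly sampling a topology, a
#'   signed interaction matrix and a growth-rate vector, and solving the
#'   equilibrium linear system. Degenerate (ill-conditioned) draws are
#'   excluded from both numerator and denominator and reported separately.
#' @name lv_experiments
NULL

# shared replicate driver; returns per-replicate feasibility, abundances,
# roles and leading Jacobian real parts as requested.
mc_replicates <- function(config, n_reps, seed = NULL,
                          keep_x = FALSE, keep_roles = FALSE,
                          spectra = FALSE) {
  stopifnot(inherits(config, "lv_config"), n_reps >= 1)
  S <- config$S
  structural <- config$rates$kind == "structural"
  A_bar <- NULL
  r_structural <- NULL
  if (structural) {
    A_bar <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, S, 0),
                       mean_interaction_matrix(config))
    r_structural <- structural_growth_rates(A_bar, config$theta, config$C,
                                            S, config$delta)
  }
  feasible <- rep(NA, n_reps)
  degenerate <- logical(n_reps)
  X <- if (keep_x) matrix(NA_real_, n_reps, S) else NULL
  roles <- if (keep_roles) matrix(NA_integer_, n_reps, S) else NULL
  leading <- if (spectra) rep(NA_real_, n_reps) else NULL

  for (k in seq_len(n_reps)) {
    draw <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, S, k), {
      t <- generate_topology(config)
      Ak <- sample_interaction_matrix(t, config$interaction, config$sigma)
      r <- if (structural) r_structural
           else draw_growth_rates(config$rates, S)
      list(t = t, A = Ak, r = r)
    })
    eq <- solve_equilibrium(draw$A, draw$r, theta = config$theta,
                            delta = config$delta)
    degenerate[k] <- eq$degenerate
    if (!eq$degenerate) {
      feasible[k] <- eq$feasible
      if (keep_x) X[k, ] <- eq$x_star
      if (spectra) {
        J <- community_jacobian(eq, draw$A, theta = config$theta,
                                delta = config$delta)
        leading[k] <- spectral_stability(J)$leading
      }
    }
    if (keep_roles && config$model != "may_directed")
      roles[k, ] <- as.integer(trophic_roles(draw$t)$role)
  }
  list(feasible = feasible, degenerate = degenerate, X = X, roles = roles,
       leading = leading)
}

check_degenerate_rate <- function(n_degenerate, n_total) {
  if (n_degenerate > 0.05 * n_total)
    warning(sprintf(paste0("%d of %d draws (%.1f%%) were degenerate ",
                           "(ill-conditioned); estimates may be biased. ",
                           "The system is close to structural instability ",
                           "(sigma ~ |theta|)."),
                    n_degenerate, n_total, 100 * n_degenerate / n_total),
            call. = FALSE)
}

#' Estimate the feasibility probability by Monte Carlo
#'
#' Draws `n_reps` independent (topology, interaction matrix, growth rates)
#' triples from the configuration, solves each equilibrium and reports the
#' fraction of strictly feasible draws among the non-degenerate ones, with
#' a 95% confidence interval (Wilson score by default).
#'
#' @param config an [community_config()].
#' @param n_reps number of Monte-Carlo replicates (>= 1; published curves
#'   use 1000).
#' @param seed optional base seed; replicate `k` runs under a child seed
#'   derived from `(seed, S, k)` so results are reproducible and curves
#'   extensible.
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @param level confidence level.
#' @return an `lv_ps_estimate`: list with `n_total`, `n_degenerate`,
#'   `n_feasible`, `p_hat`, `ci_low`, `ci_high`, `config`.
#' @examples
#' cfg <- community_config("may", S = 15, delta = 0.5)
#' estimate_feasibility(cfg, n_reps = 50, seed = 1)
#' @export
estimate_feasibility <- function(config, n_reps = 1000, seed = NULL,
                                 ci_method = c("wilson", "wald"),
                                 level = 0.95) {
  ci_method <- match.arg(ci_method)
  res <- mc_replicates(config, n_reps, seed)
  n_deg <- sum(res$degenerate)
  n_eff <- n_reps - n_deg
  if (n_eff == 0)
    stop_param("all ", n_reps, " draws were degenerate; the estimate is ",
               "undefined (sigma is too close to |theta|)")
  check_degenerate_rate(n_deg, n_reps)
  k <- sum(res$feasible, na.rm = TRUE)
  ci <- if (ci_method == "wilson") wilson_ci(k, n_eff, level)
        else wald_ci(k, n_eff, level)
  structure(
    list(n_total = n_reps, n_degenerate = n_deg, n_feasible = k,
         p_hat = k / n_eff, ci_low = unname(ci["lower"]),
         ci_high = unname(ci["upper"]), level = level,
         ci_method = ci_method, seed = seed, config = config),
    class = "lv_ps_estimate"
  )
}

#' @export
print.lv_ps_estimate <- function(x, ...) {
  cat(sprintf(paste0("<lv_ps_estimate> P_S = %.4f [%.4f, %.4f] ",
                     "(%d/%d feasible, %d degenerate)\n"),
              x$p_hat, x$ci_low, x$ci_high, x$n_feasible,
              x$n_total - x$n_degenerate, x$n_degenerate))
  invisible(x)
}

#' Feasibility probability across a species-richness grid
#'
#' One [estimate_feasibility()] per value of `S`, sharing the base seed
#' (child seeds mix in `S`, so adding grid points never changes existing
#' ones). When the configuration admits the closed-form moderate-regime
#' prediction (May model, structural rates, `delta = 1/2`,
#' `sigma < |theta|`) the analytic value is included.
#'
#' @inheritParams estimate_feasibility
#' @param S_values increasing vector of species richness values.
#' @return a tidy data frame with one row per `S`: `S`, `n`, `n_feasible`,
#'   `n_degenerate`, `p_hat`, `ci_low`, `ci_high`, `p_analytic`.
#' @export
feasibility_curve <- function(config, S_values, n_reps = 1000, seed = NULL,
                              ci_method = c("wilson", "wald")) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(S_values) >= 1, !is.unsorted(S_values))
  analytic_ok <- config$model == "may_directed" &&
    config$rates$kind == "structural" && config$delta == 0.5 &&
    config$sigma > 0 && config$sigma < abs(config$theta)
  rows <- lapply(S_values, function(S) {
    cfg <- config
    cfg$S <- as.integer(S)
    est <- estimate_feasibility(cfg, n_reps, seed, ci_method)
    data.frame(
      S = S, n = est$n_total, n_feasible = est$n_feasible,
      n_degenerate = est$n_degenerate, p_hat = est$p_hat,
      ci_low = est$ci_low, ci_high = est$ci_high,
      p_analytic = if (analytic_ok)
        analytic_feasibility_probability(S, config$sigma, config$theta)
      else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Per-species abundance statistics across replicates
#'
#' Runs the Monte-Carlo pipeline keeping every equilibrium, and summarises
#' each species' abundance across non-degenerate replicates: mean, sd, and
#' the envelope (min and max). Species of structured webs are identified
#' by their hierarchy rank (index 1 = base of the hierarchy, `S` = top);
#' the trophic role assigned to a species is its modal role across
#' replicates. Role-pooled standard deviations (the mean of the
#' per-species sds within each role) are attached as attribute `role_sd`.
#'
#' @inheritParams estimate_feasibility
#' @param n_reps number of replicates (>= 2).
#' @param feasible_only restrict the summary to feasible draws (default
#'   `FALSE`: all non-degenerate draws contribute).
#' @return a data frame with columns `species`, `rank`, `role`, `mean`,
#'   `sd`, `min`, `max`; attributes `role_sd` and `n_used`.
#' @export
abundance_summary <- function(config, n_reps = 1000, seed = NULL,
                              feasible_only = FALSE) {
  stopifnot(n_reps >= 2)
  predweb <- config$model != "may_directed"
  res <- mc_replicates(config, n_reps, seed, keep_x = TRUE,
                       keep_roles = predweb)
  check_degenerate_rate(sum(res$degenerate), n_reps)
  keep <- !res$degenerate
  if (feasible_only) keep <- keep & !is.na(res$feasible) & res$feasible
  X <- res$X[keep, , drop = FALSE]
  if (nrow(X) < 2)
    stop_param("fewer than two usable replicates; cannot summarise")
  S <- config$S
  role <- rep(NA_character_, S)
  if (predweb) {
    lev <- c("basal", "intermediate", "top")
    role <- apply(res$roles[keep, , drop = FALSE], 2, function(z) {
      lev[which.max(tabulate(z, nbins = 3))]
    })
  }
  out <- data.frame(
    species = seq_len(S),
    rank = if (predweb) (S - seq_len(S)) / (S - 1) else NA_real_,
    role = role,
    mean = colMeans(X),
    sd = apply(X, 2, stats::sd),
    min = apply(X, 2, min),
    max = apply(X, 2, max)
  )
  if (predweb) {
    pooled <- tapply(out$sd, factor(out$role, levels = lev), mean)
    attr(out, "role_sd") <- data.frame(role = names(pooled),
                                       pooled_sd = as.numeric(pooled))
  }
  attr(out, "n_used") <- nrow(X)
  out
}

#' Stability conditional on feasibility
#'
#' Among the non-degenerate draws of a Monte-Carlo run, computes the
#' leading real part of the community-matrix spectrum for every draw and
#' reports the fraction of feasible draws that are spectrally stable,
#' together with the leading-real-part samples for feasible and infeasible
#' draws. When no draw is feasible the conditional fraction is `NA` and
#' only the marginal spectra are reported.
#'
#' @inheritParams estimate_feasibility
#' @return list with `n_feasible`, `n_stable_given_feasible`,
#'   `fraction_stable_given_feasible`, `leading_feasible`,
#'   `leading_infeasible`, `n_degenerate`.
#' @export
stability_given_feasibility <- function(config, n_reps = 1000, seed = NULL) {
  res <- mc_replicates(config, n_reps, seed, spectra = TRUE)
  check_degenerate_rate(sum(res$degenerate), n_reps)
  ok <- !res$degenerate
  feas <- ok & !is.na(res$feasible) & res$feasible
  infeas <- ok & !feas
  lead_f <- res$leading[feas]
  n_stable <- sum(lead_f < 0)
  list(
    n_feasible = sum(feas),
    n_stable_given_feasible = n_stable,
    fraction_stable_given_feasible =
      if (sum(feas) > 0) n_stable / sum(feas) else NA_real_,
    leading_feasible = lead_f,
    leading_infeasible = res$leading[infeas],
    n_degenerate = sum(res$degenerate)
  )
}
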