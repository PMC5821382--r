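#' @title Signed random interaction strengths
#' @description Decorate a topology with signed per-capita interaction
#'   strengths. Magnitudes are Gaussian (May's mixture model) or
#'   folded-Gaussian `|N(0, sigma)|` (sign-constrained interaction types);
#'   the overall strength is scaled downstream by the linkage-density
#'   factor `(C S)^-delta`.
#' @name lv_interaction
NULL

INTERACTION_TYPES <- c("may_mixture", "mutualism", "competition", "predation")

#' Linkage-density normalization factor
#'
#' Interaction strengths are divided by the linkage density `C S` raised to
#' the power `delta`, i.e. multiplied by `(C S)^-delta`. `delta = 0` leaves
#' strengths untouched (strong interactions); `delta = 1/2` is the Wigner
#' scaling under which May's criterion is size-independent (moderate);
#' `delta = 1` divides by the full linkage density (weak interactions).
#'
#' @param C connectance parameter.
#' @param S species richness.
#' @param delta scaling exponent in \[0, 1\].
#' @return the positive scalar `(C S)^-delta`.
#' @examples
#' normalization_factor(0.25, 100, 0.5) # 1/5
#' @export
normalization_factor <- function(C, S, delta) {
  if (!is.numeric(delta) || length(delta) != 1 || delta < 0 || delta > 1)
    stop_param("`delta` must lie in [0, 1]")
  if (C * S <= 0) stop_param("`C * S` must be positive")
  (C * S)^(-delta)
}

check_type_topology <- function(type, t) {
  ok <- switch(type,
    may_mixture = t$model == "may_directed",
    mutualism = ,
    competition = t$model == "unstructured_paired",
    predation = t$model %in% c("unstructured_paired", STRUCTURED_MODELS),
    FALSE
  )
  if (!ok)
    stop_param("interaction type '", type,
               "' is incompatible with topology model '", t$model, "'")
}

#' Sample a signed interaction matrix on a topology
#'
#' * `may_mixture` (directed topology): every supported entry is an
#'   independent centred Gaussian `N(0, sigma)`, yielding a mixture of
#'   interaction types including commensalism and amensalism.
#' * `mutualism` / `competition` (paired topology): both directions of a
#'   linked pair are independent `+|N(0, sigma)|` / `-|N(0, sigma)|`.
#' * `predation` on a paired topology: a fair coin decides the predator of
#'   each linked pair; the predator side gets `+|N(0, sigma)|`, the prey
#'   side `-|N(0, sigma)|`, magnitudes independent.
#' * `predation` on a structured topology (cascade/niche/nested-hierarchy):
#'   entries of the predation adjacency get `+|N(0, sigma)|` and the
#'   transposed entries `-|N(0, sigma)|`; the interaction matrix is the sum
#'   of the two.
#'
#' @param t an `lv_topology`.
#' @param type interaction type: `"may_mixture"`, `"mutualism"`,
#'   `"competition"` or `"predation"`.
#' @param sigma strength standard deviation (>= 0; 0 gives a zero matrix,
#'   useful as a no-interaction control).
#' @return an `lv_interaction` holding the dense matrix `A`, the type,
#'   `sigma` and the topology.
#' @export
sample_interaction_matrix <- function(t, type = INTERACTION_TYPES, sigma = 0.4) {
  type <- match.arg(type)
  stopifnot(inherits(t, "lv_topology"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop_param("`sigma` must be a single non-negative number")
  check_type_topology(type, t)
  S <- t$S
  A <- matrix(0, S, S)
  if (type == "may_mixture") {
    idx <- which(t$alpha == 1L)
    A[idx] <- stats::rnorm(length(idx), 0, sigma)
  } else if (type %in% c("mutualism", "competition")) {
    sgn <- if (type == "mutualism") 1 else -1
    idx <- which(t$alpha == 1L)
    A[idx] <- sgn * abs(stats::rnorm(length(idx), 0, sigma))
  } else if (t$model == "unstructured_paired") { # unstructured predation
    pairs <- which(t$alpha == 1L & upper.tri(t$alpha), arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      coin <- stats::rbinom(nrow(pairs), 1L, 0.5)
      mag_up <- abs(stats::rnorm(nrow(pairs), 0, sigma))
      mag_lo <- abs(stats::rnorm(nrow(pairs), 0, sigma))
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (coin[k] == 1L) { # i is the predator
          A[i, j] <- mag_up[k]; A[j, i] <- -mag_lo[k]
        } else {
          A[i, j] <- -mag_up[k]; A[j, i] <- mag_lo[k]
        }
      }
    }
  } else { # structured predation: alpha and t(alpha) have disjoint support
    idx <- which(t$alpha == 1L)
    A[idx] <- abs(stats::rnorm(length(idx), 0, sigma))
    idx_t <- which(t(t$alpha) == 1L)
    A[idx_t] <- -abs(stats::rnorm(length(idx_t), 0, sigma))
  }
  structure(list(A = A, type = type, sigma = sigma, topology = t),
            class = "lv_interaction")
}

#' Mean interaction strength between interacting species
#'
#' The expectation of a nonzero entry of the interaction matrix: 0 for the
#' May mixture and for predation (positive and negative sides balance),
#' `+sigma sqrt(2/pi)` for mutualism and `-sigma sqrt(2/pi)` for
#' competition (folded-normal mean).
#'
#' @param type interaction type.
#' @param sigma strength standard deviation.
#' @return a scalar mean strength.
#' @export
mean_interaction_strength <- function(type = INTERACTION_TYPES, sigma = 0.4) {
  type <- match.arg(type)
  switch(type,
    may_mixture = 0,
    predation = 0,
    mutualism = sigma * sqrt(2 / pi),
    competition = -sigma * sqrt(2 / pi)
  )
}

#' Entrywise mean of the random interaction matrix
#'
#' Returns the expectation (or a Monte-Carlo estimate) of the interaction
#' matrix `A`, averaged over both the random topology and the random
#' strengths. Unstructured models admit closed forms: the May mixture and
#' paired predation average to zero, mutualism/competition to
#' `+-C sigma sqrt(2/pi)` off the diagonal. Structured predation webs have
#' rank-dependent link probabilities with no convenient closed form, so
#' they are averaged over `M` independent draws (species are aligned by
#' hierarchy rank across draws).
#'
#' @param config an [community_config()] object.
#' @param M number of Monte-Carlo draws for structured models (default
#'   taken from the configuration, itself defaulting to 200).
#' @param method `"auto"` (closed form where exact, Monte Carlo otherwise),
#'   `"closed_form"` or `"monte_carlo"`.
#' @return an S x S numeric matrix.
#' @export
mean_interaction_matrix <- function(config, M = config$M,
                                    method = c("auto", "closed_form", "monte_carlo")) {
  method <- match.arg(method)
  stopifnot(inherits(config, "lv_config"))
  if (!is.numeric(M) || length(M) != 1 || M < 1)
    stop_param("`M` must be a positive integer")
  S <- config$S
  structured <- config$model %in% STRUCTURED_MODELS
  if (method == "closed_form" && structured)
    stop_param("no closed form for structured topologies; use Monte Carlo")
  if (method == "auto") method <- if (structured) "monte_carlo" else "closed_form"

  if (method == "closed_form") {
    m <- config$C * mean_interaction_strength(config$interaction, config$sigma)
    A_bar <- matrix(m, S, S)
    diag(A_bar) <- 0
    return(A_bar)
  }
  A_bar <- matrix(0, S, S)
  for (k in seq_len(M)) {
    t <- generate_topology(config)
    A_bar <- A_bar + sample_interaction_matrix(t, config$interaction, config$sigma)$A
  }
  A_bar / M
}

#' Export an interaction matrix
#'
#' Writes either the dense matrix (`format = "dense"`, plain CSV without
#' headers) or a weighted edge list with columns `i,j,a_ij` containing the
#' nonzero entries (1-based indices).
#'
#' @param x an `lv_interaction` or a plain numeric matrix.
#' @param path output file.
#' @param format `"edgelist"` or `"dense"`.
#' @export
write_interaction_matrix <- function(x, path, format = c("edgelist", "dense")) {
  format <- match.arg(format)
  A <- if (inherits(x, "lv_interaction")) x$A else x
  if (format == "dense") {
    utils::write.table(A, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(A != 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1], j = idx[, 2], a_ij = A[idx])
    df <- df[order(df$i, df$j), ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @export
print.lv_interaction <- function(x, ...) {
  nz <- sum(x$A != 0)
  cat(sprintf("<lv_interaction> %s on %s web, S = %d, sigma = %g, %d nonzero entries\n",
              x$type, x$topology$model, x$topology$S, x$sigma, nz))
  invisible(x)
}
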