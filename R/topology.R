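#' @title Food-web topologies
#' @description Constructors and generators for the binary interaction
#'   topologies used throughout the package. A topology is the support of
#'   the interaction matrix: `alpha[i, j] = 1` means species `i` receives a
#'   direct per-capita effect from species `j`; for predation webs it means
#'   `i` preys upon `j`. Intraspecific effects are never part of `alpha`
#'   (they are carried by the self-regulation coefficient `theta`), so the
#'   diagonal is always zero.
#' @name lv_topology
NULL

TOPOLOGY_MODELS <- c(
  "may_directed", "unstructured_paired",
  "cascade", "niche", "nested_hierarchy"
)
STRUCTURED_MODELS <- c("cascade", "niche", "nested_hierarchy")

new_topology <- function(S, alpha, model, C_target, niche = NULL) {
  stopifnot(
    is.matrix(alpha), nrow(alpha) == S, ncol(alpha) == S,
    all(alpha %in% c(0, 1)), all(diag(alpha) == 0),
    model %in% TOPOLOGY_MODELS
  )
  structure(
    list(S = as.integer(S), alpha = alpha, model = model,
         C_target = C_target, niche = niche),
    class = "lv_topology"
  )
}

check_SC <- function(S, C) {
  if (!is.numeric(S) || length(S) != 1 || S < 2 || S != round(S))
    stop_param("`S` must be a single integer >= 2")
  if (!is.numeric(C) || length(C) != 1 || C <= 0 || C >= 1)
    stop_param("`C` must lie strictly between 0 and 1")
}

#' Generate an unstructured (Erdos-Renyi) topology
#'
#' In `directed` mode (May's random model) each off-diagonal entry of the
#' adjacency matrix is set to one independently with probability `C`. In
#' `paired` mode (mutualism, competition, unstructured predation) each
#' unordered species pair is linked in both directions with probability `C`,
#' giving a symmetric 0/1 pattern.
#'
#' @param S species richness (integer >= 2).
#' @param C connectance parameter in (0, 1).
#' @param mode `"directed"` or `"paired"`.
#' @return an `lv_topology`.
#' @examples
#' set.seed(1)
#' t <- generate_unstructured(30, 0.25, "directed")
#' connectance(t)
#' @export
generate_unstructured <- function(S, C, mode = c("directed", "paired")) {
  mode <- match.arg(mode)
  check_SC(S, C)
  alpha <- matrix(0L, S, S)
  if (mode == "directed") {
    off <- which(row(alpha) != col(alpha))
    alpha[off] <- stats::rbinom(length(off), 1L, C)
    model <- "may_directed"
  } else {
    up <- which(upper.tri(alpha))
    alpha[up] <- stats::rbinom(length(up), 1L, C)
    alpha <- alpha + t(alpha)
    model <- "unstructured_paired"
  }
  new_topology(S, alpha, model, C)
}

#' Generate a cascade-model food web
#'
#' Species are placed on a strict hierarchy (index `S` highest); each
#' ordered pair with `i > j` is linked (`i` preys on `j`) independently with
#' probability `C`, so the predation adjacency is strictly lower-triangular
#' and the realized connectance `L / (S (S - 1))` targets `C / 2`.
#'
#' @inheritParams generate_unstructured
#' @return an `lv_topology` with model tag `"cascade"`.
#' @export
generate_cascade <- function(S, C) {
  check_SC(S, C)
  alpha <- matrix(0L, S, S)
  lo <- which(lower.tri(alpha))
  alpha[lo] <- stats::rbinom(length(lo), 1L, C)
  new_topology(S, alpha, "cascade", C)
}

#' Generate a niche-model food web
#'
#' Each species receives a niche value `n_i ~ U(0, 1)` (species are stored
#' in increasing niche order, so index 1 is the lowest-niche species and
#' index `S` the highest). A diet-range fraction `x ~ Beta(1, 1/C - 1)`
#' gives the range `r_i = x n_i`, and the diet of species `i` is every other
#' species whose niche value falls in an interval of width `r_i` centred at
#' `c_i ~ U(r_i / 2, n_i - r_i / 2)`. The interval therefore lies wholly
#' below the consumer's own niche value: diets are contiguous (interval
#' webs), the predation graph is acyclic, cannibalistic self-links cannot
#' arise, and the expected realized connectance is exactly `C / 2`.
#'
#' The smallest-niche species is assigned an empty diet, guaranteeing at
#' least one basal species. Duplicated niche values (a probability-zero
#' event) are redrawn. By default species left without any link are kept
#' and classified as (isolated) basal species downstream: redrawing them
#' until connected conditions the web on connectedness and inflates the
#' realized connectance by several standard errors, destroying the
#' unbiasedness of the generator. Set `redraw_isolated = TRUE` to redraw
#' such species until every one has at least one link.
#'
#' @inheritParams generate_unstructured
#' @param redraw_isolated redraw species with no links until none remain
#'   (biases connectance upward; default `FALSE`).
#' @return an `lv_topology` with model tag `"niche"`; the niche values are
#'   kept in the `niche` field.
#' @export
generate_niche <- function(S, C, redraw_isolated = FALSE) {
  check_SC(S, C)
  beta <- 1 / C - 1
  n <- sort(stats::runif(S))
  x <- stats::rbeta(S, 1, beta)
  draw_centres <- function() {
    r <- x * n
    stats::runif(S, r / 2, n - r / 2)
  }
  ctr <- draw_centres()

  build <- function() {
    alpha <- matrix(0L, S, S)
    r <- x * n
    for (i in 2:S) { # species 1 (smallest niche) keeps an empty diet
      prey <- which(n >= ctr[i] - r[i] / 2 & n <= ctr[i] + r[i] / 2)
      prey <- prey[prey != i]
      alpha[i, prey] <- 1L
    }
    alpha
  }

  for (attempt in 1:1000) {
    alpha <- build()
    bad <- which(duplicated(n) | duplicated(n, fromLast = TRUE))
    if (redraw_isolated)
      bad <- union(bad, which(rowSums(alpha) + colSums(alpha) == 0))
    if (length(bad) == 0) break
    n[bad] <- stats::runif(length(bad))
    x[bad] <- stats::rbeta(length(bad), 1, beta)
    ord <- order(n)
    n <- n[ord]; x <- x[ord]
    ctr <- draw_centres()
  }
  new_topology(S, alpha, "niche", C, niche = n)
}

#' Generate a nested-hierarchy food web
#'
#' Species receive sorted niche values as in the niche model. The number of
#' prey of species `i` is `b_i = round(x_i n_i (S - 1))` with
#' `x ~ Beta(1, 1/C - 1)` (so the expected connectance is `C / 2`), capped
#' at `i - 1` so that diets contain lower-ranked species only and the web is
#' acyclic. Prey are chosen sequentially: a random lower-ranked species is
#' picked; if it already has consumers, the new consumer joins that consumer
#' group and subsequent prey are drawn from the group's pooled diet
#' (restricted to lower-ranked species); once the pool is exhausted the
#' remaining prey are drawn uniformly from the unchosen lower-ranked
#' species. This mimics the phylogenetic "inherited diet" constraint that
#' relaxes the strict intervality of the niche model.
#'
#' @inheritParams generate_unstructured
#' @return an `lv_topology` with model tag `"nested_hierarchy"`.
#' @export
generate_nested_hierarchy <- function(S, C) {
  check_SC(S, C)
  beta <- 1 / C - 1
  n <- sort(stats::runif(S))
  x <- stats::rbeta(S, 1, beta)
  b <- pmin(round(x * n * (S - 1)), seq_len(S) - 1L)
  alpha <- matrix(0L, S, S)
  for (i in seq_len(S)) {
    if (b[i] == 0) next
    prey <- integer(0)
    pool <- integer(0)       # group's pooled prey, once a group is joined
    in_group <- FALSE
    while (length(prey) < b[i]) {
      if (!in_group) {
        cand <- setdiff(seq_len(i - 1L), prey)
        j <- if (length(cand) == 1) cand else sample(cand, 1)
        prey <- c(prey, j)
        consumers <- which(alpha[, j] == 1L)
        if (length(consumers) > 0) {
          in_group <- TRUE
          pool <- unique(unlist(lapply(consumers, function(k) which(alpha[k, ] == 1L))))
          pool <- setdiff(pool[pool < i], prey)
        }
      } else if (length(pool) > 0) {
        j <- if (length(pool) == 1) pool else sample(pool, 1)
        pool <- setdiff(pool, j)
        prey <- c(prey, j)
      } else {
        cand <- setdiff(seq_len(i - 1L), prey)
        j <- if (length(cand) == 1) cand else sample(cand, 1)
        prey <- c(prey, j)
      }
    }
    alpha[i, prey] <- 1L
  }
  new_topology(S, alpha, "nested_hierarchy", C, niche = n)
}

#' Connectance of a topology
#'
#' Returns `L / (S (S - 1))` where `L` counts the stored directed links of
#' the adjacency matrix. For the directed May model this targets `C`; for
#' paired unstructured webs both directions of an edge are stored, so it
#' also targets `C`; for the structured predation models each trophic link
#' is stored once and the target is `C / 2`. Set `ordered = FALSE` to count
#' each unordered pair of a symmetric web once instead.
#'
#' @param t an `lv_topology`.
#' @param ordered count stored directed links (default) rather than
#'   unordered pairs.
#' @return the realized connectance.
#' @export
connectance <- function(t, ordered = TRUE) {
  stopifnot(inherits(t, "lv_topology"))
  L <- sum(t$alpha)
  if (!ordered && t$model == "unstructured_paired") L <- L / 2
  L / (t$S * (t$S - 1))
}

#' Classify species into trophic roles
#'
#' A species is *basal* when it has no prey (an empty row of the predation
#' adjacency; isolated species are classified basal and flagged), *top* when
#' it has at least one prey and no predators (empty column), and
#' *intermediate* otherwise. The hierarchy rank maps index to `[0, 1]` with
#' 0 for the top of the hierarchy (index `S`) and 1 for the base (index 1),
#' matching the convention that structured webs store species in increasing
#' niche order.
#'
#' @param t a predation topology (cascade, niche, nested-hierarchy or
#'   paired predation web).
#' @return a data frame with columns `species`, `rank`, `role` and
#'   `isolated`.
#' @export
trophic_roles <- function(t) {
  stopifnot(inherits(t, "lv_topology"))
  if (t$model == "may_directed")
    stop_param("trophic roles are defined for predation topologies, ",
               "not the directed May model")
  S <- t$S
  n_prey <- rowSums(t$alpha)
  n_pred <- colSums(t$alpha)
  role <- ifelse(n_prey == 0, "basal",
                 ifelse(n_pred == 0, "top", "intermediate"))
  data.frame(
    species = seq_len(S),
    rank = (S - seq_len(S)) / (S - 1),
    role = factor(role, levels = c("basal", "intermediate", "top")),
    isolated = n_prey == 0 & n_pred == 0
  )
}

#' @export
print.lv_topology <- function(x, ...) {
  cat(sprintf("<lv_topology> %s web, S = %d, C_target = %g, realized C = %.4f\n",
              x$model, x$S, x$C_target, connectance(x)))
  invisible(x)
}
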