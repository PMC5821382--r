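#' @title Lotka-Volterra equilibria
#' @description The community dynamics are
#'   `dx/dt = x o (r + (theta I + (C S)^-delta A) x)`; the coexistence
#'   equilibrium is the solution of the linear system
#'   `(theta I + (C S)^-delta A) x = -r` and is *feasible* when every
#'   component is strictly positive.
#' @name lv_equilibrium
NULL

# effective community matrix theta*I + (CS)^-delta * A
effective_matrix <- function(A, theta, C, S, delta) {
  if (theta >= 0) stop_param("`theta` must be negative (self-regulation)")
  f <- normalization_factor(C, S, delta)
  M <- f * A
  diag(M) <- diag(M) + theta
  M
}

unpack_A <- function(A, C = NULL, S = NULL) {
  if (inherits(A, "lv_interaction")) {
    list(A = A$A, C = A$topology$C_target, S = A$topology$S)
  } else {
    stopifnot(is.matrix(A), nrow(A) == ncol(A))
    list(A = A, C = if (is.null(C)) stop_param("`C` required with a plain matrix") else C,
         S = if (is.null(S)) nrow(A) else S)
  }
}

#' Mean structural growth-rate vector
#'
#' The deterministic growth rates that place the mean-field equilibrium
#' exactly at the all-ones abundance vector, i.e.
#' `r = -(theta I + (C S)^-delta A_bar) 1`. This is the vector most
#' favourable to feasibility: on average the equilibrium sits as far as
#' possible from the boundary of the positive orthant. For structured
#' predation webs the resulting vector contains negative entries for
#' consumers (predators starve without prey).
#'
#' @param A_bar mean interaction matrix (see [mean_interaction_matrix()]).
#' @param theta intraspecific competition coefficient (negative).
#' @param C,S,delta scaling parameters of the community.
#' @return a length-`S` growth-rate vector.
#' @export
structural_growth_rates <- function(A_bar, theta, C, S = nrow(A_bar), delta) {
  if (theta >= 0) stop_param("`theta` must be negative")
  f <- normalization_factor(C, S, delta)
  as.numeric(-(theta + f * (A_bar %*% rep(1, S))))
}

#' Solve for the coexistence equilibrium
#'
#' Solves `(theta I + (C S)^-delta A) x = -r` by a dense linear solve. The
#' reciprocal condition number of the system matrix is estimated
#' (LAPACK `dgecon` via [Matrix::rcond()]); a draw whose condition exceeds
#' `cond_threshold`, whose solve fails, or whose residual exceeds
#' `residual_tol` is flagged *degenerate* rather than raising an error, so
#' Monte-Carlo pipelines can count such draws separately. Near
#' `sigma ~ |theta|` the system approaches structural instability and
#' degenerate draws become common.
#'
#' @param A an `lv_interaction` or a plain S x S matrix (then supply `C`).
#' @param r growth-rate vector.
#' @param theta intraspecific competition coefficient (negative).
#' @param delta interaction-strength scaling exponent.
#' @param C,S community parameters, inferred from an `lv_interaction`.
#' @param cond_threshold condition-number threshold for degeneracy.
#' @param residual_tol maximum allowed infinity-norm residual of
#'   `M x + r`, relative to `max(1, max|r|)`.
#' @return an `lv_equilibrium`: list with `x_star`, `feasible`,
#'   `condition`, `degenerate` and `residual`.
#' @examples
#' A <- matrix(c(0, -0.5, 0.5, 0), 2, 2)
#' solve_equilibrium(A, r = c(-0.25, 1), theta = -1, delta = 0, C = 0.5)
#' @export
solve_equilibrium <- function(A, r, theta = -1, delta = 0.5, C = NULL, S = NULL,
                              cond_threshold = 1e12, residual_tol = 1e-9) {
  u <- unpack_A(A, C, S)
  if (length(r) != nrow(u$A)) stop_param("`r` has the wrong length")
  M <- effective_matrix(u$A, theta, u$C, u$S, delta)
  rc <- suppressWarnings(Matrix::rcond(Matrix::Matrix(M)))
  cond <- if (is.finite(rc) && rc > 0) 1 / rc else Inf
  x <- NULL
  if (cond <= cond_threshold)
    x <- tryCatch(as.numeric(solve(M, -r)), error = function(e) NULL)
  degenerate <- is.null(x)
  residual <- NA_real_
  if (!degenerate) {
    residual <- max(abs(M %*% x + r))
    if (!is.finite(residual) || residual > residual_tol * max(1, max(abs(r))))
      degenerate <- TRUE
  }
  structure(
    list(
      x_star = if (degenerate) rep(NA_real_, u$S) else x,
      feasible = if (degenerate) NA else all(x > 0),
      condition = cond,
      degenerate = degenerate,
      residual = residual
    ),
    class = "lv_equilibrium"
  )
}

#' Is an equilibrium feasible?
#'
#' Feasibility is strict positivity of every abundance; an exact zero
#' counts as infeasible. Degenerate (ill-conditioned) equilibria have no
#' defined feasibility and return `NA`.
#'
#' @param eq an `lv_equilibrium`.
#' @return `TRUE`, `FALSE`, or `NA` for degenerate input.
#' @export
is_feasible <- function(eq) {
  stopifnot(inherits(eq, "lv_equilibrium"))
  if (eq$degenerate) return(NA)
  all(eq$x_star > 0)
}

#' Community matrix (Jacobian at equilibrium)
#'
#' The Jacobian of the Lotka-Volterra dynamics evaluated at the
#' equilibrium, `J(x*) = diag(x*) (theta I + (C S)^-delta A)`. Row `i`
#' scales linearly with the abundance `x*_i`; the local-stability analysis
#' of random-matrix theory replaces this matrix by
#' `theta I + (C S)^-delta A`, discarding the dependence on `x*`.
#'
#' @inheritParams solve_equilibrium
#' @param eq a non-degenerate `lv_equilibrium` (or a bare abundance vector).
#' @return an S x S numeric matrix.
#' @export
community_jacobian <- function(eq, A, theta = -1, delta = 0.5, C = NULL, S = NULL) {
  x <- if (inherits(eq, "lv_equilibrium")) {
    if (eq$degenerate) stop_param("cannot evaluate the Jacobian of a degenerate equilibrium")
    eq$x_star
  } else as.numeric(eq)
  u <- unpack_A(A, C, S)
  if (length(x) != u$S) stop_param("abundance vector has the wrong length")
  x * effective_matrix(u$A, theta, u$C, u$S, delta)
}

#' Lotka-Volterra time derivative
#'
#' Evaluates `x o (r + (theta I + (C S)^-delta A) x)`. Used for residual
#' verification (it vanishes at a non-degenerate equilibrium), and as the
#' right-hand side of the verification ODE integration. `x = 0` is always
#' an equilibrium (extinction).
#'
#' @inheritParams solve_equilibrium
#' @param x non-negative abundance vector.
#' @return the rate-of-change vector.
#' @export
lv_derivative <- function(x, r, theta = -1, delta = 0.5, A, C = NULL, S = NULL) {
  u <- unpack_A(A, C, S)
  M <- effective_matrix(u$A, theta, u$C, u$S, delta)
  as.numeric(x * (r + M %*% x))
}

#' Integrate the Lotka-Volterra dynamics
#'
#' Adaptive integration (lsoda, absolute and relative tolerance 1e-10) of
#' the community dynamics, clipping abundances at zero. This is a
#' verification tool: for a stable feasible equilibrium, trajectories
#' started nearby must converge back to the linear-solve solution.
#'
#' @inheritParams solve_equilibrium
#' @param x0 initial abundances (non-negative).
#' @param times output times (default `seq(0, 100, by = 1)`).
#' @return the `deSolve` output matrix (time in column 1).
#' @export
integrate_lv <- function(x0, r, theta = -1, delta = 0.5, A, C = NULL, S = NULL,
                         times = seq(0, 100, by = 1)) {
  u <- unpack_A(A, C, S)
  M <- effective_matrix(u$A, theta, u$C, u$S, delta)
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(y * (r + as.numeric(M %*% y)))
  }
  deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
               rtol = 1e-10, atol = 1e-10)
}

#' Export an equilibrium as CSV
#'
#' Columns `species`, `rank`, `role`, `x_star`; trophic annotation comes
#' from the topology when available.
#'
#' @param eq an `lv_equilibrium`.
#' @param topology the `lv_topology` the equilibrium belongs to (optional;
#'   roles require a predation topology).
#' @param path output file.
#' @export
write_equilibrium <- function(eq, path, topology = NULL) {
  stopifnot(inherits(eq, "lv_equilibrium"))
  S <- length(eq$x_star)
  df <- data.frame(species = seq_len(S), rank = NA_real_,
                   role = NA_character_, x_star = eq$x_star)
  if (!is.null(topology) && topology$model != "may_directed") {
    tr <- trophic_roles(topology)
    df$rank <- tr$rank
    df$role <- as.character(tr$role)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.lv_equilibrium <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<lv_equilibrium> degenerate draw (condition ~ %.3g)\n", x$condition))
  } else {
    cat(sprintf("<lv_equilibrium> S = %d, %s, min x* = %.4g, max x* = %.4g\n",
                length(x$x_star), if (x$feasible) "feasible" else "infeasible",
                min(x$x_star), max(x$x_star)))
  }
  invisible(x)
}
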