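test_that("equilibrium solve matches hand-computed 2x2 cases", {
  A <- matrix(c(0, -0.5, 0.5, 0), 2, 2) # a12 = 0.5, a21 = -0.5
  eq <- solve_equilibrium(A, r = c(-0.25, 1), theta = -1, delta = 0, C = 0.5)
  expect_false(eq$degenerate)
  expect_equal(eq$x_star, c(0.2, 0.9), tolerance = 1e-12)
  expect_true(is_feasible(eq))

  # adjugate-oracle value for the infeasible case:
  # x = adj(M) (-r) / det(M) with M = [[-1, .5], [-.5, -1]], det = 1.25
  eq2 <- solve_equilibrium(A, r = c(1, -0.2), theta = -1, delta = 0, C = 0.5)
  expect_equal(eq2$x_star, c(0.72, -0.56), tolerance = 1e-12)
  expect_false(is_feasible(eq2))

  # zero interactions: x* = -r / theta
  eq3 <- solve_equilibrium(matrix(0, 4, 4), r = rep(1, 4), theta = -1,
                           delta = 0.5, C = 0.25)
  expect_equal(eq3$x_star, rep(1, 4))
})

test_that("feasibility is strict positivity", {
  eq <- solve_equilibrium(matrix(0, 3, 3), r = c(1, 0, 2), theta = -1,
                          delta = 0, C = 0.5)
  expect_equal(eq$x_star, c(1, 0, 2))
  expect_false(is_feasible(eq)) # an exact zero is infeasible
})

test_that("singular systems yield a degenerate flag, not an error", {
  A <- matrix(c(0, 1, 1, 0), 2, 2) # theta*I + A singular at theta = -1
  eq <- solve_equilibrium(A, r = c(1, 1), theta = -1, delta = 0, C = 0.5)
  expect_true(eq$degenerate)
  expect_true(is.na(is_feasible(eq)))
  expect_error(community_jacobian(eq, A, theta = -1, delta = 0, C = 0.5),
               "degenerate")
})

test_that("community Jacobian is diag(x*) times the effective matrix", {
  A <- matrix(c(0, -0.5, 0.5, 0), 2, 2)
  eq <- solve_equilibrium(A, r = c(-0.25, 1), theta = -1, delta = 0, C = 0.5)
  J <- community_jacobian(eq, A, theta = -1, delta = 0, C = 0.5)
  expect_equal(J, matrix(c(-0.2, -0.45, 0.1, -0.9), 2, 2), tolerance = 1e-12)
  # row i scales linearly with x*_i
  J2 <- community_jacobian(2 * eq$x_star, A, theta = -1, delta = 0, C = 0.5)
  expect_equal(J2, 2 * J)
  # zero-interaction control: J = -diag(x*)
  eq0 <- solve_equilibrium(matrix(0, 3, 3), r = rep(1, 3), theta = -1,
                           delta = 0, C = 0.5)
  expect_equal(community_jacobian(eq0, matrix(0, 3, 3), theta = -1,
                                  delta = 0, C = 0.5), -diag(3))
})

test_that("lv_derivative vanishes at equilibria and extinction", {
  set.seed(301)
  t <- generate_unstructured(10, 0.3, "directed")
  A <- sample_interaction_matrix(t, "may_mixture", 0.3)
  r <- runif(10, 0.5, 1.5)
  eq <- solve_equilibrium(A, r, theta = -1, delta = 0.5)
  d <- lv_derivative(eq$x_star, r, theta = -1, delta = 0.5, A = A)
  expect_lt(max(abs(d)), 1e-9)
  expect_equal(lv_derivative(rep(0, 10), r, theta = -1, delta = 0.5, A = A),
               rep(0, 10))
  # single-species logistic arithmetic
  expect_equal(lv_derivative(0.5, r = 1, theta = -1, delta = 0,
                             A = matrix(0, 1, 1), C = 0.5), 0.25)
})

test_that("linear-solve residuals stay below tolerance on random draws", {
  set.seed(302)
  for (k in 1:25) {
    t <- generate_unstructured(60, 0.25, "directed")
    A <- sample_interaction_matrix(t, "may_mixture", 0.4)
    r <- rnorm(60, 1, 0.5)
    eq <- solve_equilibrium(A, r, theta = -1, delta = 0.5)
    expect_false(eq$degenerate)
    expect_lt(eq$residual, 1e-9)
  }
})

test_that("structural growth rates place the mean-field equilibrium at 1", {
  # May model: A_bar = 0, so r = -theta * 1
  cfg <- baseline_config("may", S = 5, delta = 0.5)
  A_bar <- mean_interaction_matrix(cfg)
  r <- structural_growth_rates(A_bar, theta = -1, C = 0.25, S = 5, delta = 0.5)
  expect_equal(r, rep(1, 5))

  # mutualism: r_i = 1 - (S-1) f m, here S = 3
  cfg3 <- baseline_config("mutualism", S = 3, delta = 0.5)
  A_bar3 <- mean_interaction_matrix(cfg3)
  m <- 0.25 * 0.4 * sqrt(2 / pi)
  f <- normalization_factor(0.25, 3, 0.5)
  r3 <- structural_growth_rates(A_bar3, theta = -1, C = 0.25, S = 3, delta = 0.5)
  expect_equal(r3, rep(1 - 2 * f * m, 3), tolerance = 1e-12)

  # consistency: solving the mean-field system returns exactly 1
  for (model in c("mutualism", "competition")) {
    cfg10 <- baseline_config(model, S = 10, delta = 0.5)
    A_bar10 <- mean_interaction_matrix(cfg10)
    r10 <- structural_growth_rates(A_bar10, theta = -1, C = 0.25, S = 10,
                                   delta = 0.5)
    eq <- solve_equilibrium(A_bar10, r10, theta = -1, delta = 0.5, C = 0.25)
    expect_equal(eq$x_star, rep(1, 10), tolerance = 1e-9)
  }
})

test_that("structured webs get negative structural growth rates for consumers", {
  # in the moderate regime the (CS)^-1/2 scaling leaves prey income large
  # enough that high-ranked consumers need r_i < 0 to equilibrate at 1
  set.seed(303)
  cfg <- baseline_config("niche", S = 50, delta = 0.5, M = 100)
  A_bar <- mean_interaction_matrix(cfg)
  r <- structural_growth_rates(A_bar, theta = -1, C = 0.25, S = 50, delta = 0.5)
  expect_true(any(r < 0)) # predators starve without prey
  expect_gt(r[1], 0)      # the basal species grows on its own
})

test_that("ODE integration relaxes back to the linear-solve equilibrium", {
  set.seed(304)
  found <- 0
  while (found < 5) {
    t <- generate_unstructured(5, 0.5, "directed")
    A <- sample_interaction_matrix(t, "may_mixture", 0.4)
    eq <- solve_equilibrium(A, rep(1, 5), theta = -1, delta = 0.5)
    if (eq$degenerate || !eq$feasible) next
    J <- community_jacobian(eq, A, theta = -1, delta = 0.5)
    if (!spectral_stability(J)$stable) next
    found <- found + 1
    x0 <- eq$x_star * (1 + runif(5, -0.2, 0.2))
    for (chunk in 1:8) {
      out <- integrate_lv(x0, rep(1, 5), theta = -1, delta = 0.5, A = A,
                          times = c(0, 500))
      x0 <- out[nrow(out), -1]
      if (max(abs(x0 - eq$x_star)) < 1e-7) break
    }
    expect_lt(max(abs(x0 - eq$x_star)), 1e-6)
  }
})

test_that("equilibria export with trophic annotation", {
  set.seed(305)
  t <- generate_cascade(10, 0.4)
  A <- sample_interaction_matrix(t, "predation", 0.2)
  eq <- solve_equilibrium(A, rep(1, 10), theta = -1, delta = 1)
  f <- tempfile(fileext = ".csv")
  write_equilibrium(eq, f, topology = t)
  df <- read.csv(f)
  expect_equal(names(df), c("species", "rank", "role", "x_star"))
  expect_equal(df$x_star, eq$x_star, tolerance = 1e-6)
  expect_true(all(df$role %in% c("basal", "intermediate", "top")))
})
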