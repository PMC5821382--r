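test_that("unstructured generators respect mode, diagonal and domain", {
  set.seed(101)
  # near-complete paired graph: every pair linked
  t <- generate_unstructured(2, 1 - 1e-12, "paired")
  expect_equal(t$alpha, matrix(c(0L, 1L, 1L, 0L), 2, 2))

  for (mode in c("directed", "paired")) {
    t <- generate_unstructured(40, 0.3, mode)
    expect_true(all(diag(t$alpha) == 0))
    expect_true(all(t$alpha %in% c(0L, 1L)))
    if (mode == "paired") expect_identical(t$alpha, t(t$alpha))
  }
  expect_error(generate_unstructured(1, 0.25), "S")
  expect_error(generate_unstructured(10, 0), "C")
  expect_error(generate_unstructured(10, 1), "C")
})

test_that("directed link count matches binomial moments", {
  set.seed(102)
  n_draws <- 1000
  ones <- replicate(n_draws, sum(generate_unstructured(50, 0.25, "directed")$alpha))
  # oracle: L ~ Binomial(50*49, 0.25)
  expected <- 0.25 * 50 * 49
  se <- sqrt(50 * 49 * 0.25 * 0.75) / sqrt(n_draws)
  expect_lt(abs(mean(ones) - expected), 3 * se)
})

test_that("cascade webs are strictly lower-triangular with connectance C/2", {
  set.seed(103)
  t <- generate_cascade(30, 0.25)
  expect_true(all(t$alpha[upper.tri(t$alpha)] == 0))
  expect_true(all(diag(t$alpha) == 0))
  # two-species limit: species 2 preys on species 1 only
  t2 <- generate_cascade(2, 1 - 1e-12)
  expect_equal(t2$alpha, matrix(c(0L, 1L, 0L, 0L), 2, 2))
  # binomial oracle: L ~ Binomial(S(S-1)/2, C)
  n_draws <- 1000
  cs <- replicate(n_draws, connectance(generate_cascade(30, 0.25)))
  se <- sd(cs) / sqrt(n_draws)
  expect_lt(abs(mean(cs) - 0.125), 3 * se)
})

test_that("niche webs are interval, acyclic, with a basal species", {
  set.seed(104)
  for (k in 1:50) {
    t <- generate_niche(30, 0.25)
    expect_true(all(diag(t$alpha) == 0))
    expect_true(is_interval_web(t$alpha))
    # diets lie strictly below the consumer's niche value
    expect_true(all(t$alpha[upper.tri(t$alpha)] == 0))
    expect_true(is_acyclic(t$alpha))
    expect_equal(sum(t$alpha[1, ]), 0) # smallest-niche species: empty diet
    expect_true(any(rowSums(t$alpha) == 0))
    expect_false(is.unsorted(t$niche))
  }
})

test_that("niche connectance is an unbiased estimator of C/2", {
  set.seed(105)
  n_draws <- 1000
  cs <- replicate(n_draws, connectance(generate_niche(30, 0.25)))
  se <- sd(cs) / sqrt(n_draws)
  expect_lt(abs(mean(cs) - 0.125), 3 * se)
})

test_that("nested-hierarchy webs are acyclic with connectance near C/2", {
  set.seed(106)
  for (k in 1:50) {
    t <- generate_nested_hierarchy(30, 0.25)
    expect_true(all(diag(t$alpha) == 0))
    expect_true(all(t$alpha[upper.tri(t$alpha)] == 0))
    expect_true(is_acyclic(t$alpha))
  }
  n_draws <- 1000
  cs <- replicate(n_draws, connectance(generate_nested_hierarchy(30, 0.25)))
  se <- sd(cs) / sqrt(n_draws)
  expect_lt(abs(mean(cs) - 0.125), 3 * se)
})

test_that("acyclicity agrees with the igraph oracle on structured draws", {
  skip_if_not_installed("igraph")
  set.seed(107)
  gens <- list(generate_cascade, generate_niche, generate_nested_hierarchy)
  for (gen in gens) {
    t <- gen(25, 0.3)
    g <- igraph::graph_from_adjacency_matrix(t$alpha, mode = "directed")
    expect_true(igraph::is_dag(g))
    expect_true(is_acyclic(t$alpha))
  }
  # sanity: the helper flags a 2-cycle
  expect_false(is_acyclic(matrix(c(0, 1, 1, 0), 2, 2)))
})

test_that("generators are reproducible under identical seeds", {
  draws <- function() list(
    u = generate_unstructured(20, 0.3, "paired"),
    c = generate_cascade(20, 0.3),
    n = generate_niche(20, 0.3),
    h = generate_nested_hierarchy(20, 0.3)
  )
  set.seed(42); a <- draws()
  set.seed(42); b <- draws()
  expect_identical(a, b)
})

test_that("connectance follows the link-count definition", {
  t <- generate_unstructured(5, 0.5, "directed")
  t$alpha <- matrix(0L, 5, 5) # empty web
  expect_equal(connectance(t), 0)
  t$alpha <- matrix(1L, 5, 5) - diag(5) # complete directed web
  expect_equal(connectance(t), 1)
  t3 <- generate_unstructured(3, 0.5, "directed")
  t3$alpha <- matrix(0L, 3, 3); t3$alpha[1, 2] <- 1L; t3$alpha[3, 1] <- 1L
  expect_equal(connectance(t3), 1 / 3)
  # pairs-once convention for symmetric webs
  tp <- generate_unstructured(3, 0.5, "paired")
  tp$alpha <- matrix(c(0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L), 3, 3)
  expect_equal(connectance(tp, ordered = FALSE), connectance(tp) / 2)
})

test_that("trophic roles follow prey/predator emptiness", {
  # 3-species chain: 3 preys on 2 preys on 1
  t <- generate_cascade(3, 0.5)
  t$alpha <- matrix(0L, 3, 3); t$alpha[2, 1] <- 1L; t$alpha[3, 2] <- 1L
  roles <- trophic_roles(t)
  expect_equal(as.character(roles$role), c("basal", "intermediate", "top"))
  expect_equal(roles$rank, c(1, 0.5, 0))
  expect_false(any(roles$isolated))

  # isolated species classified basal and flagged
  t$alpha <- matrix(0L, 3, 3); t$alpha[3, 1] <- 1L
  roles <- trophic_roles(t)
  expect_equal(as.character(roles$role), c("basal", "basal", "top"))
  expect_true(roles$isolated[2])

  # roles are undefined for the directed May model
  td <- generate_unstructured(5, 0.3, "directed")
  expect_error(trophic_roles(td), "predation")

  # cascade draw: top species have prey but no predators
  set.seed(108)
  tc <- generate_cascade(30, 0.25)
  roles <- trophic_roles(tc)
  tops <- which(roles$role == "top")
  expect_true(all(colSums(tc$alpha)[tops] == 0))
  expect_true(all(rowSums(tc$alpha)[tops] > 0))
})
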