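test_that("morphogen profile follows the exponential decay law", {
  f <- field_config()
  M <- morphogen_profile(f)
  expect_equal(M[12], exp(-1))            # c = 12/30, h = 0.4
  expect_equal(M[30], exp(-2.5))          # c = 1
  expect_true(all(diff(M) < 0))
  expect_equal(morphogen_profile(field_config(A0 = 0)), rep(0, 30))
  expect_error(field_config(h = 0), "positive")
  expect_error(field_config(N = 1), ">= 2")
})

test_that("morphogen profile is strictly decreasing across parameter draws", {
  set.seed(7)
  for (i in 1:20) {
    f <- field_config(N = sample(2:80, 1), A0 = runif(1, 0.1, 5),
                      h = runif(1, 0.05, 3))
    expect_true(all(diff(morphogen_profile(f)) < 0))
  }
})

test_that("activation sigmoid has the right threshold, value, and limits", {
  p <- model_params()
  expect_equal(activation(1, p), 0.5)                 # threshold a/b
  expect_equal(activation(0, p), 1 / (1 + exp(5)))    # ~0.006693
  expect_equal(activation(1e6, p), 1)
  expect_equal(activation(-1e6, p), 0)
  u <- seq(-5, 5, by = 0.1)
  g <- activation(u, p)
  expect_true(all(g > 0 & g < 1))
  expect_true(all(diff(g) > 0))
})

test_that("regulatory input is the weighted sum of regulators", {
  g0 <- genotype(matrix(0, 3, 4), rep(0, 3), rep(10, 3))
  expect_equal(regulatory_input(g0, c(0.3, 1, 2), 0.5), c(0, 0, 0))
  W <- matrix(0, 3, 4)
  W[1, 2] <- 2   # A self-input w_iA = 2
  W[1, 1] <- -5  # morphogen weight
  g1 <- genotype(W, rep(0, 3), rep(10, 3))
  expect_equal(regulatory_input(g1, c(0.3, 0, 0), 0.5)[1], -1.9)
  u1 <- regulatory_input(g1, c(0.3, 0.1, 0.2), 0.5)
  u2 <- regulatory_input(g1, 2 * c(0.3, 0.1, 0.2), 1.0)
  expect_equal(u2, 2 * u1)
  expect_error(regulatory_input(g1, c(1, 2), 0.5), "length")
})

test_that("right-hand side matches a term-by-term hand computation", {
  f <- field_config(N = 5)
  p <- model_params()
  # uniform state: diffusion term vanishes in every cell
  W <- matrix(0, 3, 4)
  g <- genotype(W, D = rep(0.1, 3), phl = rep(10, 3))
  st <- matrix(2, 3, 5)
  d <- grn_rhs(g, st, f, p)
  expected <- activation(0, p) - log(2) / 10 * 2
  expect_equal(d, matrix(expected, 3, 5), ignore_attr = TRUE)
  # g(u) = 0.5, delta = 0.1, G = 2 -> dG/dt = 0.5 - 0.2 = 0.3
  W2 <- matrix(0, 3, 4); W2[, 1] <- 1 / morphogen_profile(f)[1] # u = 1 in cell 1
  g2 <- genotype(pmin(W2, 10), D = rep(0, 3), phl = rep(log(2) / 0.1, 3))
  st2 <- matrix(2, 3, 5)
  d2 <- grn_rhs(g2, st2, f, p)
  expect_equal(d2[1, 1], 0.5 - 0.1 * 2, ignore_attr = TRUE)
})

test_that("integration honours the initial condition and decay fixed point", {
  g <- genotype(matrix(0, 3, 4), D = rep(0.05, 3), phl = rep(5, 3))
  s <- integrate_grn(g, times = c(0, 250, 500))
  expect_true(s$ok)
  expect_equal(series_slice(s, 0), matrix(0.1, 3, 30,
                                          dimnames = list(c("A", "B", "C"),
                                                          NULL)))
  # no spatial coupling of a uniform field: fixed point g(0)/delta
  fp <- activation(0, model_params()) / (log(2) / 5)
  final <- series_slice(s, 500)
  expect_equal(max(abs(final - fp)), 0, tolerance = 1e-5)
  expect_lt(max(apply(final, 1, var)), 1e-12)
})

test_that("with D = 0 and no morphogen input all cells evolve identically", {
  set.seed(11)
  W <- matrix(runif(12, -3, 3), 3, 4)
  W[, 1] <- 0
  g <- genotype(W, D = c(0, 0, 0), phl = runif(3, 5, 50))
  s <- integrate_grn(g, times = c(0, 100, 250, 500))
  expect_true(s$ok)
  for (k in seq_along(s$times)) {
    sl <- series_slice(s, s$times[k])
    expect_lt(max(apply(sl, 1, var)), 1e-12)
  }
})

test_that("concentrations stay non-negative within solver tolerance", {
  for (g in make_genotype_batch(6, seed = 3)) {
    s <- integrate_grn(g, times = c(0, 100, 250, 500))
    if (s$ok) expect_gt(min(s$conc), -1e-6)
  }
})

test_that("adaptive and Euler integrations agree on random genotypes", {
  for (g in make_genotype_batch(3, seed = 8)) {
    s <- integrate_grn(g, times = c(0, 500))
    e <- euler_integrate(g, times = c(0, 500), dt = 1e-3)
    expect_true(s$ok)
    expect_lt(max(abs(series_slice(s, 500) - series_slice(e, 500))), 1e-3)
  }
})

test_that("steady-state detection applies the strict 0.001 criterion", {
  g <- genotype(matrix(0, 3, 4), D = rep(0.05, 3), phl = rep(5, 3))
  s <- integrate_grn(g)
  st <- steady_state_reached(s)
  expect_true(st$steady)
  expect_lt(st$S, 1e-6)
  expect_error(steady_state_reached(s, t1 = 123), "not among")
})

test_that("solver failure is flagged, not raised", {
  # an integrable genotype at an absurd horizon is not obtainable, so force
  # the flag through the series constructor contract instead: a failed
  # series scores fitness 0
  bad <- stripegrn:::new_series(matrix(NA_real_, 3, 90), c(0, 250, 500),
                                field_config(), model_params(), ok = FALSE)
  expect_false(bad$ok)
  expect_identical(fitness_score(bad)$F, 0)
})
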