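make_series <- function(states, times = c(0, 250, 500), N = 30) {
  # assemble a grn_series from explicit 3xN slices (list indexed by time)
  flat <- t(vapply(times, function(t) as.numeric(t(states[[as.character(t)]])),
                  numeric(3 * N)))
  stripegrn:::new_series(flat, times, field_config(N = N), model_params(),
                         ok = TRUE)
}

test_that("steady-state filter equals the mean squared slice difference", {
  a <- matrix(0.5, 3, 30)
  s_eq <- make_series(list(`0` = a, `250` = a, `500` = a))
  expect_identical(s_filter(s_eq), 0)
  b <- a; b[1, 1] <- a[1, 1] + 0.3
  s_one <- make_series(list(`0` = a, `250` = a, `500` = b))
  expect_equal(s_filter(s_one), 0.09 / 90)
  expect_false(steady_state_reached(s_one)$steady)  # boundary case: strict <
  c2 <- a; c2[1, 1] <- a[1, 1] - 0.3
  s_neg <- make_series(list(`0` = a, `250` = a, `500` = c2))
  expect_equal(s_filter(s_neg), s_filter(s_one))    # sign-symmetric
})

test_that("heterogeneity filter is the pooled spatial variance around gene means", {
  expect_identical(p_filter(matrix(0.7, 3, 30)), 0)
  st <- matrix(0.2, 3, 30)
  st[1, ] <- rep(c(0, 1), 15)                       # gene A alternating 0/1
  expect_equal(p_filter(st), 30 * 0.25 / 90)
  st2 <- st; st2[2, ] <- st2[2, ] + 5               # shift one gene
  expect_equal(p_filter(st2), p_filter(st))
})

test_that("profile discretization bins into 1..10 by normalized ceiling", {
  v <- c(0, 0.5, 1, 2)
  expect_identical(discretize_profile(v), c(1L, 3L, 5L, 10L))
  expect_identical(discretize_profile(rep(0, 5)), rep(1L, 5))
  expect_error(discretize_profile(c(-1, 2)), "non-negative")
  expect_identical(max(discretize_profile(runif(30))), 10L)
})

test_that("pattern score matches the Manhattan-distance formula", {
  tgt <- target_pattern(30)
  expect_identical(tgt$band, 11:20)
  perfect <- rep(0, 30); perfect[11:20] <- 1
  expect_equal(pf_eff(perfect, tgt), 1)
  expect_equal(pf_eff(rep(1, 30), tgt), 1 - 180 / 270)  # 20 cells off by 9
  inverted <- rep(1, 30); inverted[11:20] <- 0
  expect_equal(pf_eff(inverted, tgt), 0)                # D_obs = D_max = 270
  expect_identical(pf_eff(rep(0, 30), tgt), 0)          # degenerate profile
  # invariance to positive rescaling
  set.seed(2)
  v <- runif(30)
  expect_equal(pf_eff(3.7 * v, tgt), pf_eff(v, tgt))
})

test_that("quality transforms hit their half-saturation points and limits", {
  expect_equal(q1(0.1), 0.5)
  expect_equal(q2(0.1), 0.5)
  expect_identical(q1(0), 0)
  expect_identical(q2(0), 1)
  expect_equal(q1(0.2), 1024 / 1025)
  expect_equal(q2(0.001), 0.01 / (1e-6 + 0.01))
  P <- seq(0, 1, by = 0.01)
  expect_true(all(diff(q1(P)) >= 0))
  expect_true(all(diff(q2(P)) <= 0))
})

test_that("composite fitness multiplies the filters and picks the best gene", {
  a <- matrix(0.5, 3, 30)
  s_uniform <- make_series(list(`0` = a, `250` = a, `500` = a))
  expect_identical(fitness_score(s_uniform)$F, 0)   # P = 0 -> Q1 = 0
  # synthetic sharp stripe in gene C, steady and heterogeneous
  st <- matrix(0.001, 3, 30)
  st[3, 11:20] <- 3
  s_str <- make_series(list(`0` = st, `250` = st, `500` = st))
  rep <- fitness_score(s_str)
  expect_identical(rep$output_gene, 3L)
  expect_equal(rep$PF_eff, 1)
  expect_gt(rep$F, 0.95)
  # relabeling genes leaves F unchanged (max over genes)
  st_sw <- st[c(3, 2, 1), ]
  s_sw <- make_series(list(`0` = st_sw, `250` = st_sw, `500` = st_sw))
  expect_equal(fitness_score(s_sw)$F, rep$F)
})

test_that("fitness of simulated genotypes stays in [0, 1]", {
  for (g in make_genotype_batch(5, seed = 21)) {
    f <- evaluate_genotype(g)$F
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})
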