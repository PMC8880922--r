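test_that("interaction perturbations scale one weight at a time by 20%", {
  W <- matrix(0, 3, 4)
  W[1, 1] <- 2; W[2, 2] <- -5; W[3, 4] <- 9.5
  g <- genotype(W, rep(0.01, 3), rep(10, 3))
  vars <- perturb_interactions(g)
  expect_identical(length(vars), 6L)        # 2 per nonzero weight
  w11 <- sort(vapply(vars, function(v) v$W[1, 1], numeric(1)))
  expect_equal(unique(w11), c(1.6, 2, 2.4))
  # clipping keeps the genotype in the declared space
  w34 <- vapply(vars, function(v) v$W[3, 4], numeric(1))
  expect_equal(max(w34), 10)                # 9.5 * 1.2 clipped
  # purity: the source genotype is untouched
  expect_equal(g$W[1, 1], 2)
  expect_identical(length(perturb_interactions(make_flat_null())), 0L)
  expect_identical(length(perturb_interactions(g, include_morphogen = FALSE)),
                   4L)
})

test_that("class representative follows the mean-configuration rule", {
  base <- make_reference_i3ffl()
  shift <- function(d) { g <- base; g$W[1, 1] <- g$W[1, 1] + d; g }
  members <- list(shift(-1), shift(0), shift(1))
  rep3 <- class_representative(members)
  expect_equal(rep3$W[1, 1], base$W[1, 1])  # middle member is closest to mean
  expect_identical(class_representative(members[1]), members[[1]])
})

test_that("robustness scoring applies the 0.95 pass / 0.5 robust rule", {
  rs <- robustness_score(make_reference_i3ffl())
  expect_identical(rs$n_variants, 6L)
  expect_gte(rs$score, 0); expect_lte(rs$score, 1)
  expect_identical(rs$robust, rs$score >= 0.5)
  expect_equal(subgraph_robustness(c(0.2, 0.6, 1), c(FALSE, TRUE, TRUE)), 0.8)
  expect_true(is.na(subgraph_robustness(c(0.2), c(FALSE))))
})

test_that("environmental assays degenerate to baseline at zero variation", {
  g <- make_reference_i3ffl()
  base_f <- evaluate_genotype(g)$F
  set.seed(2)
  for (what in c("A0", "h", "init")) {
    f <- environmental_robustness(g, what = what, n_assays = 3, cv = 0)
    expect_equal(f, rep(base_f, 3), tolerance = 1e-12)
  }
})

test_that("environmental draws are truncated and seeded-reproducible", {
  g <- make_reference_i3ffl()
  set.seed(7)
  f1 <- environmental_robustness(g, what = "h", n_assays = 5, cv = 3)
  set.seed(7)
  f2 <- environmental_robustness(g, what = "h", n_assays = 5, cv = 3)
  expect_identical(f1, f2)          # huge CV exercises the positive floor
  expect_true(all(is.finite(f1)))
})

test_that("diffusion independence compares the zero-diffusion fitness", {
  di <- diffusion_independence(make_reference_i3ffl())
  expect_true(di$independent)       # this design needs no transport
  expect_gte(di$fitness, 0.9)
})

test_that("gradient re-anchoring preserves the endpoint concentrations", {
  base <- field_config()
  f30 <- rescale_gradient(30, base)
  expect_equal(f30$A0, 1)
  expect_equal(f30$h, 0.4)
  f10 <- rescale_gradient(10, base)
  expect_equal(f10$h, 0.9 / (2.5 - 1 / 12), tolerance = 1e-9)
  Mb <- morphogen_profile(base)
  for (N in c(10, 20, 40, 50)) {
    fN <- rescale_gradient(N, base)
    MN <- morphogen_profile(fN)
    expect_lt(abs(MN[1] - Mb[1]), 1e-9)
    expect_lt(abs(MN[N] - Mb[30]), 1e-9)
  }
  expect_error(rescale_gradient(1), ">= 2")
})

test_that("field-size scan reproduces baseline at N = 30 and degenerates on ties", {
  g <- make_reference_i3ffl()
  base_f <- evaluate_genotype(g)$F
  scan <- field_size_scan(list(g, g), sizes = c(30, 10))
  expect_equal(scan$fitness[1, "N30"], base_f, ignore_attr = TRUE)
  expect_equal(scan$fitness[1, ], scan$fitness[2, ])
  # identical fitness vectors: every principal component has zero variance
  expect_lt(max(scan$pca$sdev), 1e-12)
})
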