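test_that("sign extraction and string encoding round-trip", {
  g <- make_reference_i3ffl()
  s <- signify(g)
  expect_identical(s[1, 1], 1L)
  expect_identical(s[2, 1], -1L)
  expect_identical(signify(matrix(0, 3, 4)), matrix(0L, 3, 4,
    dimnames = list(c("A", "B", "C"), c("M", "A", "B", "C"))))
  expect_identical(sign(-3.2), -1); expect_identical(sign(0.001), 1)
  str <- topology_string(s)
  expect_identical(nchar(str), 12L)
  expect_identical(parse_topology(str), s)
  expect_error(parse_topology("abc"), "12 characters")
})

test_that("canonical form is invariant across the whole orbit", {
  set.seed(101)
  for (i in 1:40) {
    m <- rand_sign_matrix()
    canon <- canonicalize(m)
    for (iso in all_isomorphs(m)) {
      expect_identical(unname(canonicalize(iso)), unname(canon))
    }
  }
})

test_that("classification agrees with brute-force pairwise isomorphism", {
  set.seed(77)
  mats <- replicate(120, rand_sign_matrix(p_zero = 0.55), simplify = FALSE)
  cat <- classify_topologies(mats)
  # same partition: identical co-membership for every pair
  lab_pkg <- integer(length(mats))
  for (ci in seq_along(cat$members)) lab_pkg[cat$members[[ci]]] <- ci
  lab_ref <- partition_brute(mats)
  expect_identical(outer(lab_pkg, lab_pkg, "=="), outer(lab_ref, lab_ref, "=="))
  expect_identical(sum(cat$classes$abundance), length(mats))
  expect_equal(sum(cat$classes$p), 1)
  expect_true(all(diff(cat$classes$abundance) <= 0))
})

test_that("catalog semantics: counts, order invariance, empty input", {
  a <- make_reference_i3ffl()
  b <- a
  b$W <- b$W[c(2, 1, 3), c(1, 3, 2, 4)]  # relabel genes A <-> B
  dimnames(b$W) <- dimnames(a$W)
  c0 <- make_flat_null()
  cat1 <- classify_topologies(list(a, b, c0))
  expect_identical(cat1$classes$abundance, c(2L, 1L))
  cat2 <- classify_topologies(list(c0, b, a))
  expect_identical(cat1$classes$canonical, cat2$classes$canonical)
  expect_identical(nrow(classify_topologies(list())$classes), 0L)
})

test_that("Shannon entropy matches hand-computed distributions", {
  expect_identical(shannon_entropy(c(5)), 0)
  expect_equal(shannon_entropy(c(2, 2)), 1)
  expect_equal(shannon_entropy(c(2, 1, 1)), 1.5)
  expect_error(shannon_entropy(integer()), "empty")
})

test_that("entropy is bounded by log2 of items and of classes", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    mats <- replicate(n, rand_sign_matrix(), simplify = FALSE)
    cat <- classify_topologies(mats)
    H <- shannon_entropy(cat)
    expect_lte(H, log2(n) + 1e-12)
    expect_lte(H, log2(nrow(cat$classes)) + 1e-12)
  }
})

test_that("entropy null behaves at its degenerate and bounded extremes", {
  set.seed(9)
  one <- entropy_null(n_matrices = 1, n_samples = 5)
  expect_equal(one$entropies, rep(0, 5))
  small <- entropy_null(n_matrices = 40, n_samples = 5)
  expect_true(all(small$entropies <= log2(40)))
  expect_lte(small$ci[1], small$ci[2])
})

test_that("complexity index follows the degree formula", {
  i3 <- matrix(0L, 3, 4)
  i3[1, 1] <- 1L; i3[2, 2] <- 1L; i3[2, 1] <- -1L  # M->A, A->B, M-|B
  expect_equal(complexity_index(i3), 6)            # degrees (2,2,2)
  expect_equal(complexity_index(matrix(0, 3, 4)), 0)
  lone <- matrix(0L, 3, 4); lone[1, 1] <- 1L       # single edge: degrees 1,1
  expect_equal(complexity_index(lone), 0)
  self <- matrix(0L, 3, 4); self[1, 2] <- 1L       # self-loop counts 2
  expect_equal(complexity_index(self), 2)
})
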