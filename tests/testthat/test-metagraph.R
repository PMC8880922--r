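test_that("orbit Hamming distance reproduces hand-computed cases", {
  a <- matrix(0L, 3, 4); a[1, 1] <- 1L; a[2, 2] <- 1L
  # isomorph of a: relabel genes
  b <- all_isomorphs(a)[[4]]
  expect_identical(orbit_hamming(a, b), 0)
  gain <- a; gain[3, 1] <- -1L              # one interaction gained
  expect_identical(orbit_hamming(a, gain), 1)
  flip <- a; flip[1, 1] <- -1L              # one sign flip
  expect_identical(orbit_hamming(a, flip), 2)
})

test_that("orbit Hamming distance is a pseudometric", {
  set.seed(41)
  for (i in 1:120) {
    x <- rand_sign_matrix(); y <- rand_sign_matrix(); z <- rand_sign_matrix()
    dxy <- orbit_hamming(x, y)
    expect_identical(dxy, orbit_hamming(y, x))
    expect_lte(dxy, orbit_hamming(x, z) + orbit_hamming(z, y))
    expect_identical(orbit_hamming(x, x), 0)
    expect_identical(dxy, orbit_hamming_brute(x, y))
  }
})

test_that("metagraph edges respect the neighbourhood radius", {
  base <- matrix(0L, 3, 4); base[1, 1] <- 1L; base[2, 2] <- 1L
  gain <- base; gain[2, 1] <- -1L      # distance 1 from base
  flip <- base; flip[1, 1] <- -1L      # distance 2 from base
  gs <- lapply(list(base, gain, flip), function(m)
    genotype(m, rep(0.01, 3), rep(10, 3)))
  cat <- classify_topologies(gs)
  g1 <- build_metagraph(cat, k = 1)
  g2 <- build_metagraph(cat, k = 2)
  key <- function(m) topology_string(canonicalize(m))
  e1 <- igraph::as_edgelist(g1); e2 <- igraph::as_edgelist(g2)
  pair_in <- function(el, a, b)
    any((el[, 1] == a & el[, 2] == b) | (el[, 1] == b & el[, 2] == a))
  expect_true(pair_in(e1, key(base), key(gain)))
  expect_false(pair_in(e1, key(base), key(flip)))
  expect_true(pair_in(e2, key(base), key(flip)))
  # k = 1 edges are a subset of k = 2 edges
  expect_true(all(apply(e1, 1, function(r) pair_in(e2, r[1], r[2]))))
})

test_that("graph descriptors match closed forms on known graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$abundance <- 1
  d <- metagraph_descriptors(k4)
  expect_equal(d$density, 1)
  expect_equal(d$clustering, 1)
  expect_equal(d$main_diameter, 1)
  p3 <- igraph::make_graph(~ a - b, b - c)
  dp <- metagraph_descriptors(p3)
  expect_equal(dp$avg_degree, 4 / 3)
  expect_equal(dp$main_diameter, 2)
  expect_equal(dp$density * (3 - 1), dp$avg_degree)  # identity
  expect_error(metagraph_descriptors(igraph::make_empty_graph(0)), "empty")
})

test_that("degree statistics recover perfect rank correlations", {
  g <- igraph::make_graph(~ a - b, a - c, a - d, b - c)
  deg <- igraph::degree(g)
  igraph::V(g)$abundance <- deg * 10          # perfectly monotone
  # 4 vertices leave too few degree bins for the Poisson fit: warned + NA
  expect_warning(st <- degree_statistics(g), "bins")
  expect_equal(st$spearman_rho, 1)
  expect_true(is.na(st$chisq))
  igraph::V(g)$abundance <- max(deg) + 1 - deg  # reversed ranks
  st2 <- suppressWarnings(degree_statistics(g))
  expect_equal(st2$spearman_rho, -1)
})

test_that("Poisson goodness-of-fit runs on a large random graph", {
  set.seed(8)
  g <- igraph::sample_gnp(400, 0.01)
  igraph::V(g)$abundance <- 1
  st <- degree_statistics(g)
  expect_gte(st$chisq, 0)
  expect_gte(st$df, 1)
  expect_true(st$p_value >= 0 && st$p_value <= 1)
})

test_that("communities split two cliques and never span components", {
  g <- two_clique_graph(4)
  igraph::V(g)$abundance <- 1
  cm <- metagraph_communities(g)
  expect_identical(cm$n_communities, 2L)
  expect_identical(length(unique(cm$membership[1:4])), 1L)
  expect_identical(length(unique(cm$membership[5:8])), 1L)
  expect_gt(cm$modularity, 0)  # better than the one-block partition
  disc <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  cmd <- metagraph_communities(disc)
  expect_false(cmd$membership[1] == cmd$membership[4])
})
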