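#' Orbit Hamming distance between sign topologies
#'
#' `min` over all gene relabelings of `sum_ij |sgn(w_ij^A) - sgn(w_ij^B)|`.
#' A gained or removed interaction contributes 1; a sign flip contributes 2.
#' Zero iff the topologies are isomorphic, so the distance is a pseudometric
#' on sign matrices and a metric on isomorphism classes.
#'
#' @param a,b sign-topology matrices (or genotypes).
#' @return non-negative integer.
#' @export
orbit_hamming <- function(a, b) {
  va <- topo_vec(a)
  vb <- topo_vec(b)
  min(vapply(.perm_index, function(idx) sum(abs(va[idx] - vb)), numeric(1)))
}

# n x n orbit-distance matrix between the canonical topologies of a catalog
orbit_distance_matrix <- function(catalog) {
  vs <- t(vapply(catalog$topologies, topo_vec, integer(12)))
  n <- nrow(vs)
  dmat <- matrix(Inf, n, n)
  for (idx in .perm_index) {
    vp <- vs[, idx, drop = FALSE]
    dperm <- matrix(0, n, n)
    for (p in 1:12)
      dperm <- dperm + abs(outer(vp[, p], vs[, p], "-"))
    dmat <- pmin(dmat, dperm)
  }
  # enforce exact symmetry (min over permutations is one-sided per entry)
  dmat <- pmin(dmat, t(dmat))
  dimnames(dmat) <- list(catalog$classes$canonical, catalog$classes$canonical)
  dmat
}

#' Build the neutral network (metagraph) of topology classes
#'
#' Nodes are topology isomorphism classes; two classes are joined iff their
#' orbit Hamming distance is positive and at most `k`. `k = 1` is the
#' neutral network proper (classes connected by the gain or removal of a
#' single interaction); `k = 2` additionally joins classes reachable by a
#' sign flip or two gains/losses.
#'
#' @param catalog a `topology_catalog`.
#' @param k neighbourhood radius, 1 or 2.
#' @return an `igraph` undirected graph with vertex attributes `name`
#'   (canonical string), `class_id`, `abundance`.
#' @export
build_metagraph <- function(catalog, k = 1) {
  if (!k %in% c(1, 2)) stop("k must be 1 or 2")
  dmat <- orbit_distance_matrix(catalog)
  adj <- (dmat > 0 & dmat <= k) * 1
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::V(g)$class_id <- catalog$classes$class_id
  igraph::V(g)$abundance <- catalog$classes$abundance
  g
}

#' Descriptors of a metagraph
#'
#' Average vertex degree (`2E/V`), edge density (`avg_degree / (V - 1)`),
#' average local clustering coefficient (isolated/degree-1 vertices count
#' 0), average shortest-path length over reachable pairs, and the diameter
#' and average path length of the largest connected component.
#'
#' @param graph an `igraph` graph (as from [build_metagraph()]).
#' @return list with `n_nodes`, `n_edges`, `avg_degree`, `density`,
#'   `clustering`, `avg_path_length`, `main_component_size`,
#'   `main_diameter`, `main_avg_path_length`.
#' @export
metagraph_descriptors <- function(graph) {
  V <- igraph::vcount(graph)
  if (V == 0) stop("empty graph")
  E <- igraph::ecount(graph)
  avg_deg <- 2 * E / V
  comps <- igraph::components(graph)
  main <- igraph::induced_subgraph(graph,
                                   which(comps$membership ==
                                           which.max(comps$csize)))
  list(n_nodes = V, n_edges = E, avg_degree = avg_deg,
       density = if (V > 1) avg_deg / (V - 1) else 0,
       clustering = igraph::transitivity(graph, type = "localaverage",
                                         isolates = "zero"),
       avg_path_length = igraph::mean_distance(graph, unconnected = TRUE),
       main_component_size = igraph::vcount(main),
       main_diameter = igraph::diameter(main, unconnected = FALSE),
       main_avg_path_length = igraph::mean_distance(main, unconnected = TRUE))
}

#' Degree-distribution fit and abundance-degree correlation
#'
#' Fits the vertex-degree histogram to a Poisson law with rate equal to the
#' mean degree via a Pearson chi-square goodness-of-fit test (adjacent bins
#' merged until every expected count is at least 5; degrees of freedom =
#' bins - 2 for the estimated rate), and computes the Spearman rank
#' correlation between class abundance and vertex degree.
#'
#' @param graph an `igraph` graph with an `abundance` vertex attribute (as
#'   from [build_metagraph()]).
#' @return list with `lambda`, `chisq`, `df`, `p_value` (NA with a warning
#'   if fewer than 3 usable bins), `spearman_rho`, `spearman_p`.
#' @export
degree_statistics <- function(graph) {
  deg <- igraph::degree(graph)
  n <- length(deg)
  lambda <- mean(deg)
  kmax <- max(deg)
  obs <- tabulate(deg + 1L, nbins = kmax + 1L)
  expd <- n * stats::dpois(0:kmax, lambda)
  expd[kmax + 1L] <- expd[kmax + 1L] +
    n * stats::ppois(kmax, lambda, lower.tail = FALSE)
  # merge adjacent bins (left to right) until each expected count >= 5
  mobs <- numeric(0); mexp <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (i in seq_along(obs)) {
    acc_o <- acc_o + obs[i]; acc_e <- acc_e + expd[i]
    if (acc_e >= 5) {
      mobs <- c(mobs, acc_o); mexp <- c(mexp, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0 && length(mexp) > 0) {
    mobs[length(mobs)] <- mobs[length(mobs)] + acc_o
    mexp[length(mexp)] <- mexp[length(mexp)] + acc_e
  }
  if (length(mobs) < 3) {
    warning("fewer than 3 usable bins; Poisson fit skipped")
    chisq <- NA_real_; df <- NA_integer_; pval <- NA_real_
  } else {
    chisq <- sum((mobs - mexp)^2 / mexp)
    df <- length(mobs) - 2L
    pval <- stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  ab <- igraph::V(graph)$abundance
  sp <- suppressWarnings(stats::cor.test(ab, deg, method = "spearman",
                                         exact = FALSE))
  list(lambda = lambda, chisq = chisq, df = df, p_value = pval,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' Community structure of the metagraph
#'
#' Greedy modularity optimization (deterministic), reporting the membership
#' vector and the articulation ("bridge") vertices whose removal would
#' disconnect their component.
#'
#' @param graph an `igraph` graph.
#' @return list with `membership` (integer vector), `modularity`,
#'   `n_communities`, `bridges` (vertex indices of articulation points).
#' @export
metagraph_communities <- function(graph) {
  cl <- igraph::cluster_fast_greedy(igraph::simplify(graph))
  list(membership = igraph::membership(cl),
       modularity = igraph::modularity(cl),
       n_communities = length(cl),
       bridges = as.integer(igraph::articulation_points(graph)))
}
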