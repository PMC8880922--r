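# Independent oracles and small generators shared across tests.
# These deliberately avoid the package's canonical-code / census machinery:
# they re-derive the same notions from the definitions with plain loops.

# random sign matrix over {-1,0,1}
rand_sign_matrix <- function(p_zero = 0.3) {
  v <- sample(c(-1L, 1L), 12, replace = TRUE)
  v[runif(12) < p_zero] <- 0L
  matrix(v, 3, 4, dimnames = list(c("A", "B", "C"), c("M", "A", "B", "C")))
}

# all six gene relabelings of a 3x4 sign matrix, built by direct row/column
# shuffling (morphogen column fixed)
all_isomorphs <- function(m) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(perms, function(p) {
    out <- matrix(0L, 3, 4)
    for (i in 1:3) for (j in 1:4) {
      src_col <- if (j == 1) 1 else p[j - 1] + 1
      out[i, j] <- m[p[i], src_col]
    }
    out
  })
}

# are two sign matrices isomorphic? (definition: some relabeling matches)
iso_brute <- function(a, b) {
  for (m in all_isomorphs(a)) if (all(m == b)) return(TRUE)
  FALSE
}

# partition a list of sign matrices by pairwise brute-force isomorphism;
# returns an integer class label per matrix
partition_brute <- function(mats) {
  labels <- integer(length(mats))
  reps <- list()
  for (i in seq_along(mats)) {
    found <- 0L
    for (r in seq_along(reps)) {
      if (iso_brute(mats[[i]], reps[[r]])) { found <- r; break }
    }
    if (found == 0L) {
      reps[[length(reps) + 1L]] <- mats[[i]]
      found <- length(reps)
    }
    labels[i] <- found
  }
  labels
}

# brute-force orbit Hamming distance straight from the definition
orbit_hamming_brute <- function(a, b) {
  min(vapply(all_isomorphs(a), function(m) sum(abs(m - b)), numeric(1)))
}

# independent motif matcher: enumerate every role assignment explicitly
motif_present_brute <- function(sign_mat, edges) {
  roles <- setdiff(unique(c(edges$from, edges$to)), "M")
  genes <- c("A", "B", "C")
  grid <- expand.grid(rep(list(genes), length(roles)),
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    asg <- as.character(grid[r, ])
    if (anyDuplicated(asg)) next
    names(asg) <- roles
    ok <- TRUE
    for (e in seq_len(nrow(edges))) {
      from <- edges$from[e]; to <- edges$to[e]
      fn <- if (from == "M") "M" else asg[[from]]
      tn <- if (to == "M") "M" else asg[[to]]
      row <- match(tn, genes)
      col <- match(fn, c("M", genes))
      if (sign_mat[row, col] != edges$sign[e]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# two small cliques joined by a single edge (community-detection fixture)
two_clique_graph <- function(k = 4) {
  g <- igraph::disjoint_union(igraph::make_full_graph(k),
                              igraph::make_full_graph(k))
  igraph::add_edges(g, c(1, k + 1))
}
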