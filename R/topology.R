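#' Sign topology of a genotype
#'
#' The entrywise sign of the interaction matrix: +1 activation, -1
#' repression, 0 absent. The sign topology is the unit of isomorphism
#' classification; magnitudes, diffusion, and degradation are ignored.
#'
#' @param g a `grn_genotype`, or a 3x4 numeric matrix.
#' @return 3x4 integer matrix over \{-1, 0, +1\} with the genotype's
#'   row/column names.
#' @export
signify <- function(g) {
  W <- if (inherits(g, "grn_genotype")) g$W else g
  if (!is.matrix(W) || !all(dim(W) == c(3, 4)))
    stop("expected a grn_genotype or a 3x4 matrix")
  s <- sign(W)
  storage.mode(s) <- "integer"
  dimnames(s) <- list(c("A", "B", "C"), c("M", "A", "B", "C"))
  s
}

# The 6 relabelings of genes {A,B,C} as position-index vectors on the
# row-major 12-vector (rows A,B,C x cols M,A,B,C).  Under permutation sigma,
# new[i, j] = old[sigma(i), sigma(j)] with the morphogen column fixed.
.gene_perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

.perm_index <- local({
  lapply(.gene_perms, function(p) {
    idx <- integer(12)
    for (i in 1:3) for (j in 1:4) {
      src_col <- if (j == 1) 1L else p[j - 1L] + 1L
      idx[(i - 1L) * 4L + j] <- (p[i] - 1L) * 4L + src_col
    }
    idx
  })
})

# weights making the row-major base-3 code lexicographic (position 1 most
# significant); entries shifted from {-1,0,1} to {0,1,2}
.code_weights <- 3^(11:0)

topo_vec <- function(topo) as.integer(t(signify(topo)))

vec_to_topo <- function(v) {
  m <- matrix(as.integer(v), 3, 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("M", "A", "B", "C")))
  m
}

#' Canonical form of a sign topology
#'
#' Applies all 6 simultaneous row/column gene relabelings (the morphogen
#' column is never permuted) and returns the lexicographically minimal
#' matrix in row-major order. Two topologies are isomorphic iff their
#' canonical forms are identical.
#'
#' @param topo a sign-topology matrix (or genotype / weight matrix, which is
#'   signified first).
#' @return 3x4 integer sign matrix, the orbit representative.
#' @export
canonicalize <- function(topo) {
  v <- topo_vec(topo)
  codes <- vapply(.perm_index, function(idx) sum((v[idx] + 1) * .code_weights),
                  numeric(1))
  vec_to_topo(v[.perm_index[[which.min(codes)]]])
}

# integer code of the canonical form; cheap total order on isomorphism
# classes.  `vs`: n x 12 matrix of row-major sign vectors.
canonical_codes <- function(vs) {
  if (is.null(dim(vs))) vs <- matrix(vs, nrow = 1)
  codes <- rep(Inf, nrow(vs))
  for (idx in .perm_index)
    codes <- pmin(codes, (vs[, idx, drop = FALSE] + 1) %*% .code_weights)
  as.numeric(codes)
}

#' Encode / decode a sign topology as a 12-character string
#'
#' Row-major over the alphabet `-`, `0`, `+`; the interchange format used in
#' catalog exports.
#'
#' @param topo a sign-topology matrix.
#' @return single character string of length 12.
#' @export
topology_string <- function(topo) {
  paste(c("-", "0", "+")[topo_vec(topo) + 2L], collapse = "")
}

#' @rdname topology_string
#' @param s a 12-character string over `-0+`.
#' @export
parse_topology <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) != 12 || !all(ch %in% c("-", "0", "+")))
    stop("expected 12 characters over -0+")
  vec_to_topo(match(ch, c("-", "0", "+")) - 2L)
}

#' Group genotypes into topology isomorphism classes
#'
#' Computes each genotype's canonical sign topology and groups identical
#' forms. Classes are numbered in order of decreasing abundance (ties broken
#' by canonical string for determinism).
#'
#' @param genotypes list of `grn_genotype` objects, or of sign matrices.
#' @return An object of class `topology_catalog`: list with `classes` (a
#'   data.frame with `class_id`, `canonical`, `abundance`, `p`), `members`
#'   (list of member indices per class), and `topologies` (list of canonical
#'   sign matrices per class).
#' @export
classify_topologies <- function(genotypes) {
  n <- length(genotypes)
  if (n == 0) {
    return(structure(list(classes = data.frame(class_id = integer(),
                                               canonical = character(),
                                               abundance = integer(),
                                               p = numeric()),
                          members = list(), topologies = list()),
                     class = "topology_catalog"))
  }
  vs <- t(vapply(genotypes, topo_vec, integer(12)))
  codes <- canonical_codes(vs)
  groups <- split(seq_len(n), codes)
  canon <- vapply(groups, function(ix) {
    topology_string(canonicalize(vec_to_topo(vs[ix[1], ])))
  }, character(1))
  abundance <- lengths(groups)
  # ties broken by the numeric canonical code: stable across locales,
  # unlike string collation
  ord <- order(-abundance, as.numeric(names(groups)))
  groups <- groups[ord]
  canon <- canon[ord]
  abundance <- abundance[ord]
  structure(list(
    classes = data.frame(class_id = seq_along(groups), canonical = unname(canon),
                         abundance = as.integer(unname(abundance)),
                         p = as.numeric(abundance / n), row.names = NULL),
    members = unname(groups),
    topologies = unname(lapply(canon, parse_topology))
  ), class = "topology_catalog")
}

#' @export
print.topology_catalog <- function(x, ...) {
  cat("topology catalog:", sum(x$classes$abundance), "genotypes in",
      nrow(x$classes), "isomorphism classes\n")
  print(utils::head(x$classes, 10))
  invisible(x)
}

#' Shannon entropy of a class-abundance distribution
#'
#' `H = -sum p(x) log2 p(x)` over the empirical class frequencies, in bits.
#'
#' @param x a `topology_catalog`, or a vector of class counts.
#' @return non-negative scalar (bits).
#' @export
shannon_entropy <- function(x) {
  counts <- if (inherits(x, "topology_catalog")) x$classes$abundance else x
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty catalog")
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Random sign-topology matrices (entropy null model)
#'
#' Each entry is 0 with probability `p_zero` and otherwise +1 or -1 with
#' equal probability; an approximation to an unconstrained null for the
#' abundance distribution.
#'
#' @param n number of matrices.
#' @param p_zero per-entry absence probability (default 0.2).
#' @return list of 3x4 sign matrices.
#' @export
random_sign_topologies <- function(n, p_zero = 0.2) {
  lapply(seq_len(n), function(i) {
    v <- sample(c(-1L, 1L), 12, replace = TRUE)
    v[stats::runif(12) < p_zero] <- 0L
    vec_to_topo(v)
  })
}

#' Entropy of random (selection-free) topology sets
#'
#' Draws `n_samples` sets of `n_matrices` random sign topologies, classifies
#' each set, and summarizes the Shannon entropies with a mean and a 95%
#' normal confidence interval. Used as the no-selection reference against
#' which the observed catalog entropy is compared: a catalog shaped by
#' selection for stripe formation falls well below this null.
#'
#' @param n_matrices matrices per sample (the catalog size being compared).
#' @param n_samples number of samples (default 30).
#' @param p_zero per-entry absence probability of the generator.
#' @return list with `mean`, `sd`, `ci` (length-2), `entropies`.
#' @export
entropy_null <- function(n_matrices, n_samples = 30, p_zero = 0.2) {
  if (n_matrices < 1 || n_samples < 1) stop("sample sizes must be positive")
  ent <- vapply(seq_len(n_samples), function(s) {
    shannon_entropy(classify_topologies(random_sign_topologies(n_matrices,
                                                               p_zero)))
  }, numeric(1))
  m <- mean(ent)
  se <- stats::sd(ent) / sqrt(n_samples)
  list(mean = m, sd = stats::sd(ent),
       ci = c(m - 1.96 * se, m + 1.96 * se), entropies = ent)
}

#' Degree-based complexity index
#'
#' `I_vd = sum_i a_i log2(a_i)` over the nodes of the signed digraph (three
#' genes plus the morphogen), where `a_i` is the total degree (in + out)
#' and a self-loop contributes 2. Nodes of degree 0 or 1 contribute nothing.
#'
#' @param topo a sign-topology matrix (or genotype).
#' @return non-negative scalar.
#' @export
complexity_index <- function(topo) {
  s <- signify(topo) != 0L
  deg <- c(M = sum(s[, 1]),
           A = sum(s[1, ]) + sum(s[, 2]),
           B = sum(s[2, ]) + sum(s[, 3]),
           C = sum(s[3, ]) + sum(s[, 4]))
  deg <- deg[deg >= 1]
  if (length(deg) == 0) return(0)
  sum(deg * log2(deg))
}
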