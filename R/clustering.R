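#' Spatiotemporal phenotype tensor
#'
#' Integrates a genotype and samples the expression of the three genes at
#' t = 0, 10, ..., 250 (26 slices), producing the gene x time x cell tensor
#' used for phenotype clustering.
#'
#' @param g a `grn_genotype`.
#' @param field a [field_config()].
#' @param params a [model_params()].
#' @param times sampling times (default `seq(0, 250, by = 10)`).
#' @return 3 x length(times) x N numeric array, or NULL on solver failure.
#' @export
phenotype_tensor <- function(g, field = field_config(),
                             params = model_params(),
                             times = seq(0, 250, by = 10)) {
  series <- integrate_grn(g, field, params, times = times)
  if (!series$ok) return(NULL)
  series$conc
}

#' Euclidean (Frobenius) distance between phenotype tensors
#'
#' @param a,b numeric arrays of identical shape.
#' @return non-negative scalar, zero iff the tensors are equal.
#' @export
tensor_distance <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("tensor shapes differ")
  sqrt(sum((a - b)^2))
}

#' Pairwise tensor distance matrix
#'
#' @param tensors named list of equal-shape arrays.
#' @return symmetric matrix with zero diagonal.
#' @export
tensor_distance_matrix <- function(tensors) {
  n <- length(tensors)
  d <- matrix(0, n, n, dimnames = list(names(tensors), names(tensors)))
  if (n < 2) return(d)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- tensor_distance(tensors[[i]], tensors[[j]])
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}); on an additive distance
#' matrix the tree path lengths reproduce the input exactly.
#'
#' @param d symmetric distance matrix with at least 3 items (labelled rows).
#' @return an object of class `phylo` (unrooted).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 items")
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  ape::nj(d)
}

#' Cluster genotypes by spatiotemporal expression profile
#'
#' Computes the phenotype tensor of each genotype (solver failures are
#' dropped), the pairwise Frobenius distance matrix, and the NJ tree.
#'
#' @param genotypes named or unnamed list of `grn_genotype`s (at least 3
#'   integrable ones).
#' @param field,params simulation settings.
#' @return list with `tree` (`phylo`), `dist` (matrix), `labels`,
#'   `dropped` (indices that failed to integrate).
#' @export
phenotype_clustering <- function(genotypes, field = field_config(),
                                 params = model_params()) {
  labels <- names(genotypes)
  if (is.null(labels))
    labels <- vapply(seq_along(genotypes), function(i) {
      id <- genotypes[[i]]$id
      if (is.null(id)) paste0("g", i) else id
    }, character(1))
  tensors <- lapply(genotypes, phenotype_tensor, field = field,
                    params = params)
  ok <- !vapply(tensors, is.null, logical(1))
  tensors <- tensors[ok]
  names(tensors) <- labels[ok]
  d <- tensor_distance_matrix(tensors)
  list(tree = nj_tree(d), dist = d, labels = labels[ok],
       dropped = which(!ok))
}

#' Cluster topology classes by subgraph profile
#'
#' Builds the binary motif-presence matrix of the catalog, computes the
#' pairwise Hamming distances between its rows, and returns the NJ tree.
#' Classes with identical motif profiles sit at distance zero.
#'
#' @param catalog a `topology_catalog` with at least 3 classes.
#' @param motifs a motif catalog.
#' @return list with `tree` (`phylo`), `dist` (Hamming matrix), `profile`
#'   (the binary matrix).
#' @export
subgraph_profile_clustering <- function(catalog,
                                        motifs = default_motif_catalog()) {
  profs <- motif_profile_matrix(catalog, motifs)
  n <- nrow(profs)
  if (n < 3) stop("need at least 3 topology classes")
  d <- matrix(0, n, n, dimnames = list(rownames(profs), rownames(profs)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(profs[i, ] != profs[j, ])
  }
  list(tree = nj_tree(d), dist = d, profile = profs)
}
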