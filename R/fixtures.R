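#' Reference genotypes
#'
#' Hand-built and offline-tuned genotypes exercising every stage of the
#' pipeline without any external data:
#'
#' * `make_flat_null()` -- all interactions zero; the phenotype stays
#'   spatially uniform, so the heterogeneity filter (and hence the fitness)
#'   is exactly 0.
#' * `make_reference_i3ffl()` -- a type-3 incoherent feed-forward loop
#'   (morphogen activates A, A activates B, morphogen represses B) whose
#'   magnitudes were tuned once by a seeded hill climb restricted to that
#'   sign class and then frozen; it forms a clean middle stripe in gene B
#'   with fitness at least 0.95 on the default 30-cell field.
#' * `make_two_gene_gm()` -- a two-gene activator-inhibitor design
#'   (Gierer-Meinhardt-like core plus morphogen repression on both genes;
#'   gene B disconnected) that stripes in both active genes.
#' * `make_diffusion_reliant()` -- a tuned stripe-former whose pattern
#'   collapses when diffusion is switched off; the counterpart of
#'   diffusion-independent designs.
#'
#' @return a `grn_genotype`.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
make_flat_null <- function() {
  genotype(W = matrix(0, 3, 4), D = rep(0.05, 3), phl = rep(20, 3),
           id = "flat_null")
}

#' @rdname fixtures
#' @export
make_reference_i3ffl <- function() {
  W <- matrix(0, 3, 4)
  W[1, 1] <- 5.68076715882169     # M -> A activation
  W[2, 2] <- 0.270344096769113    # A -> B activation
  W[2, 1] <- -9.75230052044848    # M -| B repression
  genotype(W = W,
           D = c(0.0342151751508936, 0.000397434341721237,
                 0.0349370226496831),
           phl = c(13.2173336599953, 5.05625619087368, 7.63471329584718),
           id = "reference_i3ffl")
}

#' @rdname fixtures
#' @export
make_two_gene_gm <- function() {
  W <- matrix(0, 3, 4)
  W[1, 1] <- -6.74201905925758    # M -| A
  W[1, 2] <- -3.53521390554728    # A -| A (self-inhibition)
  W[1, 4] <- 6.38009206139483     # C -> A
  W[3, 1] <- -0.824972402621061   # M -| C
  W[3, 2] <- -4.59460082508856    # A -| C
  W[3, 4] <- 4.83758636804065     # C -> C (self-activation)
  genotype(W = W,
           D = c(0.0170609080698341, 0.0326841402100399,
                 0.00703951395116746),
           phl = c(7.19625207479112, 17.5302022276446, 13.9065391581971),
           id = "two_gene_gm")
}

#' @rdname fixtures
#' @export
make_diffusion_reliant <- function() {
  W <- matrix(c(6.16428100503981, -2.83725642133504, 2.25348692853004,
                6.24135035090148, 4.66471950523555, -0.654375525191426,
                -5.63747206702828, -3.96228548139334, 0,
                -9.49500296264887, -7.04332454130054, -9.99752986244857),
              3, 4)
  genotype(W = W,
           D = c(0.0394893441349268, 0.0961678506108001,
                 0.00539276560302824),
           phl = c(12.5541767489631, 17.7746406104416, 27.4277412262745),
           id = "diffusion_reliant")
}

#' Seeded batch of random genotypes
#'
#' Reproducible batches for property tests and null models; the RNG state
#' is restored afterwards.
#'
#' @param n batch size.
#' @param seed integer seed.
#' @param sparsity per-weight zero probability (see [random_genotype()]).
#' @return list of `n` `grn_genotype`s.
#' @export
make_genotype_batch <- function(n, seed = 1L, sparsity = 0.25) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    g <- random_genotype(sparsity)
    g$id <- sprintf("batch%d_%03d", seed, i)
    g
  })
}
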