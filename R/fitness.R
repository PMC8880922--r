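#' Steady-state filter
#'
#' `S = (1/(I*N)) * sum_i sum_n (G_i,n(t2) - G_i,n(t1))^2` with `I = 3`
#' genes; small values mean the trajectory has equilibrated between the two
#' slices. A failed integration yields `NA`.
#'
#' @param series a `grn_series` containing both slices.
#' @param t1,t2 comparison times (defaults 250 and 500).
#' @return non-negative scalar (or `NA` on solver failure).
#' @export
s_filter <- function(series, t1 = 250, t2 = 500) {
  if (!series$ok) return(NA_real_)
  d <- series_slice(series, t2) - series_slice(series, t1)
  mean(d^2)
}

#' Spatial-heterogeneity filter
#'
#' `P = (1/(I*N)) * sum_i sum_n (G_i,n - <G_i>)^2` at the final state:
#' the mean, over genes and cells, of the squared deviation of each gene
#' from its own spatial mean. Zero iff every gene is spatially uniform.
#'
#' @param state 3 x N matrix (final-time slice), or a `grn_series` whose
#'   last time slice is used.
#' @return non-negative scalar (or `NA` on solver failure).
#' @export
p_filter <- function(state) {
  if (inherits(state, "grn_series")) {
    if (!state$ok) return(NA_real_)
    state <- series_slice(state, state$times[length(state$times)])
  }
  mean((state - rowMeans(state))^2)
}

#' Target stripe pattern
#'
#' The optimal phenotype: output-gene expression above 90% of the field
#' maximum in the middle band and below 10% outside it. For the default
#' 30-cell field the band is cells 11-20; for other field sizes the middle
#' third of cells is used. In discretized form the optimal vector is 10
#' inside the band and 1 outside.
#'
#' @param N number of cells.
#' @return An object of class `target_pattern` with elements `N`, `band`
#'   (cell indices of the high region), and `optimal` (discretized vector).
#' @export
target_pattern <- function(N = 30) {
  if (N < 2) stop("N must be >= 2")
  band <- if (N == 30) 11:20 else (floor(N / 3) + 1L):ceiling(2 * N / 3)
  optimal <- rep(1L, N)
  optimal[band] <- 10L
  structure(list(N = as.integer(N), band = band, optimal = optimal),
            class = "target_pattern")
}

#' Discretize an expression profile into bins 1..10
#'
#' Normalizes by the field maximum and bins as `max(1, ceiling(10 * v /
#' v_max))`, mapping the maximum to bin 10 and (near-)zero values to bin 1.
#' An all-zero profile maps to all ones (degenerate normalization; its
#' pattern score is defined as 0 by [pf_eff()]).
#'
#' @param v numeric(N) non-negative expression profile.
#' @return integer(N) in 1..10.
#' @export
discretize_profile <- function(v) {
  if (any(v < 0)) stop("expression profile must be non-negative")
  vmax <- max(v)
  if (vmax <= 0) return(rep(1L, length(v)))
  pmax(1L, as.integer(ceiling(10 * v / vmax)))
}

#' Pattern-match score
#'
#' `PF_eff = 1 - D_obs / D_max`, where `D_obs` is the Manhattan distance
#' between the discretized profile and the discretized optimal pattern and
#' `D_max = 9 * N` (every cell maximally wrong). All-zero profiles score 0.
#'
#' @param v numeric(N) non-negative expression profile.
#' @param target a [target_pattern()] of matching length.
#' @return scalar in \[0, 1\].
#' @export
pf_eff <- function(v, target = target_pattern(length(v))) {
  if (length(v) != target$N) stop("profile length does not match target")
  if (max(v) <= 0) return(0)
  d_obs <- sum(abs(discretize_profile(v) - target$optimal))
  1 - d_obs / (9 * target$N)
}

#' Phenotype quality transforms
#'
#' `Q1(P) = P^10 / (P^10 + 0.1^10)` rewards spatial heterogeneity (sharp
#' switch around P = 0.1); `Q2(S) = 0.1^2 / (S^2 + 0.1^2)` penalizes
#' unsettled trajectories (half-value at S = 0.1).
#'
#' @param P,S non-negative filter values.
#' @return scalar in \[0, 1\].
#' @export
q1 <- function(P) P^10 / (P^10 + 0.1^10)

#' @rdname q1
#' @export
q2 <- function(S) 0.1^2 / (S^2 + 0.1^2)

#' Composite fitness of a phenotype
#'
#' `F = PF_eff * Q1(P) * Q2(S)`. The pattern score is computed for each of
#' the three genes and the best-scoring gene is taken as the output gene, so
#' a genotype striped in any gene is rewarded. Failed integrations score 0.
#'
#' @param series a `grn_series` integrated to `t_max` (slices at `t_max/2`
#'   and `t_max` must be present).
#' @param target a [target_pattern()] for the series' field size.
#' @return An object of class `fitness_report`: list with `F`, `S`, `P`,
#'   `PF_eff`, `Q1`, `Q2`, `output_gene` (1..3 or NA), `pf_per_gene`,
#'   `steady`, `ok`.
#' @export
fitness_score <- function(series, target = target_pattern(series$field$N)) {
  failed <- list(F = 0, S = NA_real_, P = NA_real_, PF_eff = NA_real_,
                 Q1 = NA_real_, Q2 = NA_real_, output_gene = NA_integer_,
                 pf_per_gene = rep(NA_real_, 3), steady = FALSE, ok = FALSE)
  class(failed) <- "fitness_report"
  if (!series$ok) return(failed)
  t_max <- series$params$t_max
  S <- s_filter(series, t1 = t_max / 2, t2 = t_max)
  final <- series_slice(series, t_max)
  # concentrations are non-negative up to solver tolerance; clamp the
  # tolerance-level undershoot, treat anything worse as a failed solve
  if (min(final) < -1e-3) return(failed)
  final <- pmax(final, 0)
  P <- p_filter(final)
  # spatial variance at solver-noise level is exactly zero in exact
  # arithmetic: snap it, so uniform phenotypes score F = 0 exactly
  if (P < 1e-12) P <- 0
  pf <- vapply(1:3, function(i) pf_eff(final[i, ], target), numeric(1))
  out_gene <- which.max(pf)
  report <- list(F = pf[out_gene] * q1(P) * q2(S), S = S, P = P,
                 PF_eff = pf[out_gene], Q1 = q1(P), Q2 = q2(S),
                 output_gene = out_gene, pf_per_gene = pf,
                 steady = S < 0.001, ok = TRUE)
  class(report) <- "fitness_report"
  report
}

#' Simulate a genotype and score it in one call
#'
#' @param g a `grn_genotype`.
#' @param field a [field_config()].
#' @param params a [model_params()].
#' @param target a [target_pattern()] (defaults to the field's size).
#' @return a `fitness_report` (see [fitness_score()]).
#' @export
evaluate_genotype <- function(g, field = field_config(),
                              params = model_params(),
                              target = target_pattern(field$N)) {
  series <- integrate_grn(g, field, params,
                          times = c(0, params$t_max / 2, params$t_max))
  fitness_score(series, target)
}

#' @export
print.fitness_report <- function(x, ...) {
  cat(sprintf("fitness F = %.4f  (PF_eff %.4f, Q1 %.4f, Q2 %.4f; output gene %s)\n",
              x$F, x$PF_eff, x$Q1, x$Q2,
              if (is.na(x$output_gene)) "-" else c("A", "B", "C")[x$output_gene]))
  invisible(x)
}
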