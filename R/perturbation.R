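#' One-at-a-time interaction perturbations
#'
#' For each nonzero interaction weight, generates two variants with that
#' weight scaled up and down by the stated relative amount (default 20%),
#' one change at a time. Scaled values falling outside \[-10, 10\] are
#' clipped back to the admissible range. By default the morphogen-input
#' column is perturbed like any other interaction; set
#' `include_morphogen = FALSE` to restrict to gene-gene interactions.
#'
#' @param g a `grn_genotype`.
#' @param rel relative perturbation (default 0.2).
#' @param include_morphogen perturb the morphogen inputs too?
#' @return list of perturbed `grn_genotype`s (2 per nonzero weight).
#' @export
perturb_interactions <- function(g, rel = 0.2, include_morphogen = TRUE) {
  cols <- if (include_morphogen) 1:4 else 2:4
  out <- list()
  for (j in cols) for (i in 1:3) {
    if (g$W[i, j] == 0) next
    for (f in c(1 + rel, 1 - rel)) {
      gv <- g
      gv$W[i, j] <- max(-10, min(10, g$W[i, j] * f))
      out[[length(out) + 1L]] <- gv
    }
  }
  out
}

#' Representative genotype of a topology class
#'
#' For classes with at least 3 members, the member whose parameter vector
#' `(W, D, phl)` is closest (Euclidean) to the class mean configuration;
#' otherwise the member with the highest fitness (recomputed if the
#' genotypes carry no `$fitness`).
#'
#' @param members list of `grn_genotype`s belonging to one class.
#' @param field,params simulation settings used if fitness must be
#'   recomputed.
#' @return one `grn_genotype` from `members`.
#' @export
class_representative <- function(members, field = field_config(),
                                 params = model_params()) {
  if (length(members) == 0) stop("empty class")
  if (length(members) == 1) return(members[[1]])
  pvec <- function(g) c(as.numeric(g$W), g$D, g$phl)
  if (length(members) >= 3) {
    mat <- vapply(members, pvec, numeric(18))
    ctr <- rowMeans(mat)
    d2 <- colSums((mat - ctr)^2)
    return(members[[which.min(d2)]])
  }
  fit <- vapply(members, function(g) {
    if (!is.null(g$fitness)) g$fitness else
      evaluate_genotype(g, field, params)$F
  }, numeric(1))
  members[[which.max(fit)]]
}

#' Parameter robustness of a topology class
#'
#' Applies [perturb_interactions()] to the class representative,
#' re-simulates every variant, and reports the proportion whose fitness
#' stays at or above the pass threshold; the class is called robust if that
#' proportion is at least `robust_cutoff`.
#'
#' @param members list of `grn_genotype`s in the class (or one genotype).
#' @param field,params simulation settings.
#' @param rel relative perturbation (default 0.2).
#' @param pass_threshold fitness needed for a variant to pass (default
#'   0.95).
#' @param robust_cutoff proportion at or above which the class is robust
#'   (default 0.5).
#' @param include_morphogen see [perturb_interactions()].
#' @return list with `score` (pass proportion), `robust`, `n_variants`,
#'   `representative`.
#' @export
robustness_score <- function(members, field = field_config(),
                             params = model_params(), rel = 0.2,
                             pass_threshold = 0.95, robust_cutoff = 0.5,
                             include_morphogen = TRUE) {
  if (inherits(members, "grn_genotype")) members <- list(members)
  repg <- class_representative(members, field, params)
  variants <- perturb_interactions(repg, rel, include_morphogen)
  if (length(variants) == 0)
    return(list(score = NA_real_, robust = NA, n_variants = 0L,
                representative = repg))
  pass <- vapply(variants, function(v)
    evaluate_genotype(v, field, params)$F >= pass_threshold, logical(1))
  score <- mean(pass)
  list(score = score, robust = score >= robust_cutoff,
       n_variants = length(variants), representative = repg)
}

#' Mean robustness of classes sharing a subgraph
#'
#' @param scores numeric vector of per-class robustness scores.
#' @param has_motif logical vector: does each class contain the subgraph?
#' @return scalar mean score over the classes containing it (NA if none).
#' @export
subgraph_robustness <- function(scores, has_motif) {
  if (length(scores) != length(has_motif)) stop("length mismatch")
  if (!any(has_motif, na.rm = TRUE)) return(NA_real_)
  mean(scores[has_motif], na.rm = TRUE)
}

#' Robustness to environmental (non-network) variation
#'
#' For each parameter class -- morphogen amplitude `A0`, gradient decay
#' `h`, or the initial concentrations -- draws perturbed values from a
#' Normal distribution centred on the baseline with coefficient of
#' variation `cv` (truncated below at a small positive floor), re-simulates
#' with one parameter class perturbed per assay, and returns the fitness
#' samples. Initial concentrations are drawn independently per gene; the
#' per-gene values scale the uniform initial condition.
#'
#' @param g a `grn_genotype`.
#' @param field baseline [field_config()].
#' @param params a [model_params()].
#' @param what one of `"A0"`, `"h"`, `"init"`.
#' @param n_assays assays (default 100).
#' @param cv coefficient of variation (default 0.3).
#' @param floor lower truncation for drawn values (default 1e-6).
#' @return numeric(n_assays) of fitness values.
#' @export
environmental_robustness <- function(g, field = field_config(),
                                     params = model_params(),
                                     what = c("A0", "h", "init"),
                                     n_assays = 100, cv = 0.3,
                                     floor = 1e-6) {
  what <- match.arg(what)
  draw <- function(mu, k = 1) pmax(floor, stats::rnorm(k, mu, cv * mu))
  vapply(seq_len(n_assays), function(i) {
    f <- field
    if (what == "A0") f$A0 <- draw(field$A0)
    if (what == "h") f$h <- draw(field$h)
    if (what == "init") {
      init <- draw(field$init_conc, 3)
      series <- integrate_grn_init(g, f, params, init)
      return(fitness_score(series)$F)
    }
    evaluate_genotype(g, f, params)$F
  }, numeric(1))
}

# integrate with per-gene initial concentrations (uniform across cells)
integrate_grn_init <- function(g, field, params, init3) {
  f <- field
  f$init_conc <- init3[1]
  series <- integrate_grn(g, f, params,
                          times = c(0, params$t_max / 2, params$t_max))
  if (length(unique(init3)) == 1) return(series)
  # general case: restage with a non-uniform y0 through the same solver
  M <- morphogen_profile(field)
  .Call(C_grn_set_model, as.numeric(t(g$W)), g$D,
        delta_rates(g, params$delta_mode), params$a, params$b, M)
  y0 <- rep(init3, each = field$N)
  times <- c(0, params$t_max / 2, params$t_max)
  sol <- try(suppressWarnings(
    deSolve::ode(y = y0, times = times, func = "C_grn_derivs", parms = NULL,
                 dllname = "stripegrn", method = "lsoda",
                 rtol = params$rtol, atol = params$atol)), silent = TRUE)
  ok <- !inherits(sol, "try-error") && nrow(sol) == length(times) &&
    all(is.finite(sol[, -1]))
  states <- if (ok) sol[, -1, drop = FALSE] else
    matrix(NA_real_, length(times), 3L * field$N)
  new_series(states, times, field, params, ok)
}

#' Is a genotype diffusion independent?
#'
#' Re-simulates with all diffusion rates set to zero; the genotype is
#' diffusion independent if it still scores at or above the fitness
#' threshold (default 0.9), i.e. the stripe does not rely on transport
#' between cells.
#'
#' @param g a `grn_genotype`.
#' @param field,params simulation settings.
#' @param threshold fitness cutoff (default 0.9).
#' @return list with `independent` (logical) and `fitness` (the no-diffusion
#'   fitness).
#' @export
diffusion_independence <- function(g, field = field_config(),
                                   params = model_params(),
                                   threshold = 0.9) {
  g0 <- g
  g0$D <- c(0, 0, 0)
  f <- evaluate_genotype(g0, field, params)$F
  list(independent = f >= threshold, fitness = f)
}

#' Re-anchor the morphogen gradient to a new field size
#'
#' Solves for `(A0', h')` such that the morphogen concentrations in the
#' first and last cells equal those of the base field:
#' `h' = (1 - 1/N) / log(M_first / M_last)` and
#' `A0' = M_last * exp(1 / h')`.
#'
#' @param N new field size (>= 2).
#' @param base the base [field_config()] whose endpoint concentrations are
#'   preserved.
#' @return a [field_config()] of size `N` with the re-anchored gradient.
#' @export
rescale_gradient <- function(N, base = field_config()) {
  if (N < 2) stop("N must be >= 2")
  M <- morphogen_profile(base)
  m_first <- M[1]
  m_last <- M[base$N]
  h2 <- (1 - 1 / N) / log(m_first / m_last)
  A02 <- m_last * exp(1 / h2)
  field_config(N = N, A0 = A02, h = h2, init_conc = base$init_conc)
}

#' Fitness across morphogenetic field sizes
#'
#' Evaluates each genotype on fields of the given sizes, re-anchoring the
#' gradient with [rescale_gradient()] and using the proportional target
#' band for each size, then summarizes the fitness vectors with a principal
#' component analysis.
#'
#' @param genotypes list of `grn_genotype`s.
#' @param sizes field sizes (default `c(10, 20, 40, 50)`).
#' @param base base [field_config()].
#' @param params a [model_params()].
#' @return list with `fitness` (genotype x size matrix), `sizes`, `pca`
#'   (a `prcomp`, NULL if fewer than 2 genotypes), `explained_variance`.
#' @export
field_size_scan <- function(genotypes, sizes = c(10, 20, 40, 50),
                            base = field_config(), params = model_params()) {
  fits <- vapply(sizes, function(N) {
    f <- if (N == base$N) base else rescale_gradient(N, base)
    tgt <- target_pattern(N)
    vapply(genotypes, function(g)
      evaluate_genotype(g, f, params, tgt)$F, numeric(1))
  }, numeric(length(genotypes)))
  fits <- matrix(fits, nrow = length(genotypes),
                 dimnames = list(NULL, paste0("N", sizes)))
  pca <- NULL
  ev <- NULL
  if (length(genotypes) >= 2) {
    pca <- stats::prcomp(fits, center = TRUE, scale. = FALSE)
    ev <- pca$sdev^2 / max(sum(pca$sdev^2), .Machine$double.eps)
  }
  list(fitness = fits, sizes = sizes, pca = pca, explained_variance = ev)
}
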