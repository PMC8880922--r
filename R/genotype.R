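#' Genotype, field, and model-parameter constructors
#'
#' A genotype is the full numeric parameterization of a three-gene regulatory
#' network (GRN): a 3x4 interaction matrix `W` (rows = regulated genes A, B,
#' C; columns = regulators M, A, B, C, where M is the morphogen), per-gene
#' diffusion rates `D`, and per-gene product half-lives `phl` from which the
#' degradation rates are derived.
#'
#' @param W 3x4 numeric matrix of interaction strengths, entries in
#'   \[-10, 10\]. Positive = activation, negative = repression, zero = no
#'   interaction. Column 1 holds the morphogen inputs `w_im`.
#' @param D numeric(3) diffusion rates in \[0, 0.1\].
#' @param phl numeric(3) gene-product half-lives in \[5, 50\].
#' @param id optional character identifier.
#' @return An object of class `grn_genotype`.
#' @export
#' @examples
#' g <- genotype(W = matrix(0, 3, 4), D = rep(0.01, 3), phl = rep(10, 3))
#' delta_rates(g)
genotype <- function(W, D, phl, id = NULL) {
  W <- matrix(as.numeric(W), 3, 4,
              dimnames = list(c("A", "B", "C"), c("M", "A", "B", "C")))
  D <- as.numeric(D)
  phl <- as.numeric(phl)
  g <- structure(list(W = W, D = D, phl = phl, id = id),
                 class = "grn_genotype")
  validate_genotype(g)
  g
}

#' @rdname genotype
#' @param g a `grn_genotype`.
#' @export
validate_genotype <- function(g) {
  stopifnot(inherits(g, "grn_genotype"))
  if (!all(is.finite(g$W)) || any(abs(g$W) > 10 + 1e-12))
    stop("interaction weights must be finite and within [-10, 10]")
  if (length(g$D) != 3 || any(g$D < 0) || any(g$D > 0.1 + 1e-12))
    stop("diffusion rates must lie in [0, 0.1]")
  if (length(g$phl) != 3 || any(g$phl < 5 - 1e-12) || any(g$phl > 50 + 1e-12))
    stop("half-lives must lie in [5, 50]")
  invisible(g)
}

#' Degradation rates of a genotype
#'
#' The default converts half-life to a first-order decay constant,
#' `delta = ln(2) / phl` (so `delta` falls in \[0.0139, 0.1386\] over the
#' admissible half-life range). The alternative mode `log2_phl` applies
#' `delta = log2(phl)` literally; it makes degradation increase with
#' half-life and is retained only for comparison.
#'
#' @param g a `grn_genotype`.
#' @param mode `"ln2_over_phl"` (default) or `"log2_phl"`.
#' @return numeric(3) of strictly positive degradation rates.
#' @export
delta_rates <- function(g, mode = c("ln2_over_phl", "log2_phl")) {
  mode <- match.arg(mode)
  if (mode == "ln2_over_phl") log(2) / g$phl else log2(g$phl)
}

#' @export
print.grn_genotype <- function(x, ...) {
  cat("GRN genotype", if (!is.null(x$id)) paste0("'", x$id, "'"), "\n")
  cat("W (rows regulated A,B,C; cols regulators M,A,B,C):\n")
  print(round(x$W, 4))
  cat("D:  ", paste(signif(x$D, 4), collapse = ", "), "\n")
  cat("phl:", paste(signif(x$phl, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Morphogenetic field configuration
#'
#' The field is a 1-D array of `N` isogenic cells under a static exponential
#' morphogen gradient `M_n = A0 * exp(-(n/N) / h)`.
#'
#' @param N number of cells (default 30).
#' @param A0 morphogen concentration at position zero (default 1).
#' @param h gradient decay parameter (default 0.4).
#' @param init_conc initial concentration of every gene product in every cell
#'   (default 0.1).
#' @return An object of class `field_config`.
#' @export
field_config <- function(N = 30, A0 = 1, h = 0.4, init_conc = 0.1) {
  if (N < 2 || N != round(N)) stop("N must be an integer >= 2")
  if (A0 < 0) stop("A0 must be non-negative")
  if (h <= 0) stop("h must be positive")
  structure(list(N = as.integer(N), A0 = A0, h = h, init_conc = init_conc),
            class = "field_config")
}

#' Dynamical-model parameters
#'
#' @param a sigmoid steepness (default 5).
#' @param b sigmoid gain (default 5; the activation threshold is `a/b` = 1).
#' @param t_max integration horizon in model time units (default 500).
#' @param rtol,atol solver tolerances.
#' @param delta_mode degradation convention, see [delta_rates()].
#' @return An object of class `model_params`.
#' @export
model_params <- function(a = 5, b = 5, t_max = 500, rtol = 1e-6, atol = 1e-6,
                         delta_mode = c("ln2_over_phl", "log2_phl")) {
  if (b == 0) stop("b must be nonzero")
  if (t_max <= 0) stop("t_max must be positive")
  structure(list(a = a, b = b, t_max = t_max, rtol = rtol, atol = atol,
                 delta_mode = match.arg(delta_mode)),
            class = "model_params")
}
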