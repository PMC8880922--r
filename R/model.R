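#' Morphogen concentration profile
#'
#' Static exponential gradient `M_n = A0 * exp(-c_n / h)` with cell index
#' `c_n = n / N` for `n = 1..N`; cell 1 therefore receives
#' `A0 * exp(-(1/N)/h)`, not `A0`.
#'
#' @param field a [field_config()].
#' @return numeric(N), strictly decreasing for positive `A0`.
#' @export
#' @examples
#' morphogen_profile(field_config())[12]  # exp(-1)
morphogen_profile <- function(field) {
  stopifnot(inherits(field, "field_config"))
  n <- seq_len(field$N)
  field$A0 * exp(-(n / field$N) / field$h)
}

#' Sigmoid activation function
#'
#' `g(u) = 1 / (1 + exp(a - b * u))`, the regulation function mapping the
#' summed regulatory input of a gene to its production rate; bounded in
#' (0, 1), equal to 0.5 at the threshold `u = a/b`.
#'
#' @param u regulatory input (any numeric).
#' @param params a [model_params()].
#' @return numeric of the same length as `u`.
#' @export
activation <- function(u, params = model_params()) {
  1 / (1 + exp(params$a - params$b * u))
}

#' Regulatory input of each gene in one cell
#'
#' `u_i = sum_j w_ij * G_j + w_im * M_n`: the weighted sum of the regulator
#' concentrations plus the morphogen term, for each of the three genes.
#'
#' @param g a `grn_genotype`.
#' @param conc numeric(3) gene-product concentrations in the cell.
#' @param morphogen scalar morphogen concentration in the cell.
#' @return numeric(3) of per-gene inputs.
#' @export
regulatory_input <- function(g, conc, morphogen) {
  if (length(conc) != 3 || length(morphogen) != 1)
    stop("conc must have length 3 and morphogen length 1")
  as.numeric(g$W %*% c(morphogen, conc))
}

#' Right-hand side of the reaction-diffusion system (reference R version)
#'
#' `d G_i,n / dt = g(u_i,n) + D_i * ((G_i,n-1 - G_i,n) + (G_i,n+1 - G_i,n))
#'  - delta_i * G_i,n` with zero-flux boundaries (the missing-neighbour term
#' is dropped in cells 1 and N). The integrators use an equivalent compiled
#' version; this one backs unit tests and exposition.
#'
#' @param g a `grn_genotype`.
#' @param state 3 x N matrix of concentrations (rows = genes).
#' @param field a [field_config()].
#' @param params a [model_params()].
#' @return 3 x N matrix of time derivatives.
#' @export
grn_rhs <- function(g, state, field, params = model_params()) {
  if (!is.matrix(state) || nrow(state) != 3 || ncol(state) != field$N)
    stop("state must be a 3 x N matrix")
  M <- morphogen_profile(field)
  u <- g$W %*% rbind(M, state)
  act <- activation(u, params)
  N <- field$N
  left <- cbind(0, state[, -N, drop = FALSE] - state[, -1, drop = FALSE])
  right <- cbind(state[, -1, drop = FALSE] - state[, -N, drop = FALSE], 0)
  act + g$D * (left + right) - delta_rates(g, params$delta_mode) * state
}

#' Integrate a genotype's dynamics over the morphogenetic field
#'
#' Solves the coupled reaction-diffusion system from the uniform initial
#' condition (`init_conc` everywhere) with an adaptive solver
#' (deSolve `lsoda`, compiled right-hand side) and returns the concentration
#' tensor at the requested output times. A solver failure (stiff blow-up,
#' non-finite state) is flagged rather than raised, so that downstream
#' scoring can assign fitness 0.
#'
#' @param g a `grn_genotype`.
#' @param field a [field_config()].
#' @param params a [model_params()].
#' @param times output times within `[0, t_max]` (default `c(0, 250, 500)`,
#'   the slices needed by the fitness filters).
#' @return An object of class `grn_series`: list with `conc` (gene x time x
#'   cell array), `times`, `ok` (logical solver status), `field`, `params`.
#' @export
integrate_grn <- function(g, field = field_config(), params = model_params(),
                          times = c(0, params$t_max / 2, params$t_max)) {
  validate_genotype(g)
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0) || any(times > params$t_max))
    stop("output times must lie within [0, t_max]")
  M <- morphogen_profile(field)
  .Call(C_grn_set_model, as.numeric(t(g$W)), g$D,
        delta_rates(g, params$delta_mode), params$a, params$b, M)
  y0 <- rep(field$init_conc, 3L * field$N)
  solve_times <- if (times[1] > 0) c(0, times) else times
  sol <- try(suppressWarnings(
    deSolve::ode(y = y0, times = solve_times, func = "C_grn_derivs",
                 parms = NULL, dllname = "stripegrn",
                 method = "lsoda", rtol = params$rtol, atol = params$atol)
  ), silent = TRUE)
  ok <- !inherits(sol, "try-error") &&
    nrow(sol) == length(solve_times) && all(is.finite(sol[, -1]))
  if (ok) {
    keep <- match(times, solve_times)
    states <- sol[keep, -1, drop = FALSE]
  } else {
    states <- matrix(NA_real_, length(times), 3L * field$N)
  }
  new_series(states, times, field, params, ok)
}

#' Fixed-step Euler integration (independent numerical oracle)
#'
#' A forward-Euler solve at a small fixed step, implemented separately from
#' the adaptive route (its own compiled loop). Used to cross-check the
#' adaptive integrator; `dt = 0.001` reproduces its output to about 1e-3.
#'
#' @inheritParams integrate_grn
#' @param dt fixed step size (default 0.001).
#' @return A `grn_series`, as for [integrate_grn()].
#' @export
euler_integrate <- function(g, field = field_config(),
                            params = model_params(),
                            times = c(0, params$t_max / 2, params$t_max),
                            dt = 1e-3) {
  validate_genotype(g)
  times <- sort(unique(as.numeric(times)))
  M <- morphogen_profile(field)
  y0 <- rep(field$init_conc, 3L * field$N)
  states <- .Call(C_euler_integrate, as.numeric(t(g$W)), g$D,
                  delta_rates(g, params$delta_mode), params$a, params$b,
                  M, y0, times, dt)
  new_series(states, times, field, params, all(is.finite(states)))
}

new_series <- function(states, times, field, params, ok) {
  conc <- array(NA_real_, dim = c(3L, length(times), field$N),
                dimnames = list(gene = c("A", "B", "C"), time = times,
                                cell = NULL))
  if (ok) {
    for (i in 1:3)
      conc[i, , ] <- states[, (i - 1L) * field$N + seq_len(field$N),
                            drop = FALSE]
  }
  structure(list(conc = conc, times = times, field = field, params = params,
                 ok = ok),
            class = "grn_series")
}

#' Extract the 3 x N state at one output time
#'
#' @param series a `grn_series`.
#' @param time one of the series' output times.
#' @return 3 x N matrix (rows = genes A, B, C).
#' @export
series_slice <- function(series, time) {
  k <- match(time, series$times)
  if (is.na(k)) stop("time ", time, " not among the series output times")
  m <- series$conc[, k, , drop = TRUE]
  matrix(m, nrow = 3, dimnames = list(c("A", "B", "C"), NULL))
}

#' Has the system reached a quasi-steady state?
#'
#' Compares the states at `t1` and `t2` through the steady-state residual
#' (mean squared difference over genes and cells) and applies the strict
#' criterion `S < 0.001`.
#'
#' @param series a `grn_series` containing both time slices.
#' @param t1,t2 comparison times (defaults 250 and 500).
#' @return list with `steady` (logical) and `S` (the residual).
#' @export
steady_state_reached <- function(series, t1 = 250, t2 = 500) {
  S <- s_filter(series, t1 = t1, t2 = t2)
  list(steady = is.finite(S) && S < 0.001, S = S)
}

#' @export
print.grn_series <- function(x, ...) {
  cat("GRN time series:", dim(x$conc)[1], "genes x", dim(x$conc)[2],
      "times x", dim(x$conc)[3], "cells;",
      if (x$ok) "solver ok" else "SOLVER FAILED", "\n")
  invisible(x)
}
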