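#' Search configuration
#'
#' Parameters of the hill-climbing Markov-chain exploration of the design
#' space. Mutation kernel: with probability 0.15 one gene's half-life is
#' redrawn, with 0.15 one diffusion rate, and with 0.7 one of the 12
#' interaction weights is either set to zero (probability 0.2 within that
#' branch) or redrawn uniformly on \[-10, 10\] (probability 0.8).
#'
#' @param n_chains number of independent chains (the full-scale study uses
#'   500; reduced runs are supported throughout).
#' @param steps_per_chain mutation-acceptance cycles per chain (full scale:
#'   50000).
#' @param save_threshold fitness above which a visited genotype is recorded
#'   (default 0.95).
#' @param p_phl,p_diff,p_weight mutation-type probabilities (must sum to 1).
#' @param p_zero probability, within a weight mutation, of zeroing the
#'   weight instead of redrawing it.
#' @param sparsity probability that each weight of a random initial genotype
#'   is zero.
#' @param seed master RNG seed (integer) or NULL to use the current RNG
#'   state.
#' @return An object of class `search_config`.
#' @export
search_config <- function(n_chains = 500, steps_per_chain = 50000,
                          save_threshold = 0.95, p_phl = 0.15, p_diff = 0.15,
                          p_weight = 0.7, p_zero = 0.2, sparsity = 0.25,
                          seed = NULL) {
  if (abs(p_phl + p_diff + p_weight - 1) > 1e-12)
    stop("mutation-type probabilities must sum to 1")
  if (save_threshold < 0 || save_threshold > 1)
    stop("save_threshold must lie in [0, 1]")
  structure(list(n_chains = n_chains, steps_per_chain = steps_per_chain,
                 save_threshold = save_threshold, p_phl = p_phl,
                 p_diff = p_diff, p_weight = p_weight, p_zero = p_zero,
                 sparsity = sparsity, seed = seed),
            class = "search_config")
}

#' Draw a random genotype
#'
#' Each weight is 0 with probability `sparsity` and otherwise uniform on
#' \[-10, 10\]; diffusion rates are uniform on \[0, 0.1\] and half-lives
#' uniform on \[5, 50\].
#'
#' @param sparsity per-weight zero probability.
#' @return a `grn_genotype`.
#' @export
random_genotype <- function(sparsity = 0.25) {
  w <- stats::runif(12, -10, 10)
  w[stats::runif(12) < sparsity] <- 0
  genotype(W = matrix(w, 3, 4), D = stats::runif(3, 0, 0.1),
           phl = stats::runif(3, 5, 50))
}

#' Mutate a genotype
#'
#' Applies exactly one mutation drawn from the kernel described in
#' [search_config()]; all range invariants are preserved by construction.
#'
#' @param g a `grn_genotype`.
#' @param config a `search_config` (only the mutation probabilities are
#'   used).
#' @return a new `grn_genotype` differing from `g` in exactly one parameter
#'   (up to the rare redraw equal to the old value).
#' @export
mutate_genotype <- function(g, config = search_config()) {
  u <- stats::runif(1)
  if (u < config$p_phl) {
    i <- sample.int(3, 1)
    g$phl[i] <- stats::runif(1, 5, 50)
  } else if (u < config$p_phl + config$p_diff) {
    i <- sample.int(3, 1)
    g$D[i] <- stats::runif(1, 0, 0.1)
  } else {
    k <- sample.int(12, 1)
    g$W[k] <- if (stats::runif(1) < config$p_zero) 0 else
      stats::runif(1, -10, 10)
  }
  g
}

#' Run one hill-climbing chain
#'
#' Starts from a random genotype and iterates: propose a single mutation,
#' evaluate fitness, accept iff the new fitness is greater than or equal to
#' the current one. Every visited (accepted) genotype with fitness at or
#' above the save threshold is recorded together with its canonical
#' topology, provided that topology has not been visited earlier in the
#' chain.
#'
#' @param config a [search_config()] (`steps_per_chain` is used).
#' @param field a [field_config()].
#' @param params a [model_params()].
#' @param init optional starting `grn_genotype` (default: random).
#' @return An object of class `chain_record`: list with `trace` (accepted
#'   fitness after each step, length `steps_per_chain + 1`), `saved` (list
#'   of `list(genotype, report, canonical)`), `final` (last genotype).
#' @export
run_chain <- function(config = search_config(), field = field_config(),
                      params = model_params(), init = NULL) {
  current <- if (is.null(init)) random_genotype(config$sparsity) else init
  rep_cur <- evaluate_genotype(current, field, params)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  saved <- list()
  # a topology is recorded the first time the chain visits it at or above
  # the save threshold; later visits (or earlier low-fitness visits) of the
  # same class do not produce duplicates
  note_state <- function(g, rep) {
    canon <- topology_string(canonicalize(signify(g)))
    novel <- !exists(canon, envir = seen, inherits = FALSE)
    if (novel && rep$F >= config$save_threshold) {
      assign(canon, TRUE, envir = seen)
      g$fitness <- rep$F
      saved[[length(saved) + 1L]] <<- list(genotype = g, report = rep,
                                           canonical = canon)
    }
  }
  note_state(current, rep_cur)
  trace <- numeric(config$steps_per_chain + 1L)
  trace[1L] <- rep_cur$F
  for (step in seq_len(config$steps_per_chain)) {
    prop <- mutate_genotype(current, config)
    rep_new <- evaluate_genotype(prop, field, params)
    if (rep_new$F >= rep_cur$F) {
      current <- prop
      rep_cur <- rep_new
      note_state(current, rep_cur)
    }
    trace[step + 1L] <- rep_cur$F
  }
  structure(list(trace = trace, saved = saved, final = current),
            class = "chain_record")
}

#' Explore the design space with independent chains
#'
#' Runs `n_chains` chains (per-chain seeds derived deterministically from
#' the master seed), pools every saved genotype, and classifies the pooled
#' set into topology isomorphism classes.
#'
#' @param config a [search_config()].
#' @param field a [field_config()].
#' @param params a [model_params()].
#' @param progress if TRUE, print per-chain progress.
#' @return list with `genotypes` (all saved genotypes, each carrying
#'   `$fitness`), `reports`, `catalog` (a `topology_catalog`), and
#'   `chain_seeds`.
#' @export
run_search <- function(config = search_config(), field = field_config(),
                       params = model_params(), progress = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_chains
  chain_seeds <- if (n > 0) sample.int(.Machine$integer.max - 1L, n) else
    integer()
  genotypes <- list()
  reports <- list()
  for (ch in seq_len(n)) {
    set.seed(chain_seeds[ch])
    rec <- run_chain(config, field, params)
    for (sv in rec$saved) {
      sv$genotype$id <- sprintf("chain%03d_%03d", ch,
                                length(genotypes) + 1L)
      genotypes[[length(genotypes) + 1L]] <- sv$genotype
      reports[[length(reports) + 1L]] <- sv$report
    }
    if (progress)
      message(sprintf("chain %d/%d: best F = %.3f, saved %d (total %d)",
                      ch, n, max(rec$trace), length(rec$saved),
                      length(genotypes)))
  }
  list(genotypes = genotypes, reports = reports,
       catalog = classify_topologies(genotypes), chain_seeds = chain_seeds)
}
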