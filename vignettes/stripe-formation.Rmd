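---
title: "Morphogen interpretation by three-gene networks: model, search, and catalog analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphogen interpretation by three-gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stripegrn)
```

## The patterning problem

A classic question in developmental biology is how a one-dimensional field
of identical cells converts a graded signal — a morphogen whose
concentration decays with position — into a sharply bounded domain of gene
expression: a stripe in the middle of the field, low expression on both
sides. `stripegrn` implements a complete computational study of this
question for three-gene regulatory networks (GRNs) in which *any* gene may
read the morphogen directly (multi-input networks), not just a designated
receiver node.

The package has four layers:

1. a reaction–diffusion model of GRN dynamics on the cell field;
2. a fitness function scoring how well a simulated phenotype matches the
   target stripe;
3. a hill-climbing Markov-chain search over the network design space that
   collects stripe-forming genotypes;
4. catalog analyses of the collected designs: isomorphism classification,
   motif census, neutral network (metagraph), entropy and complexity,
   robustness, diffusion independence, field-size scaling, and
   distance-based clustering.

## Model and assumptions

A **genotype** is `W` (a 3×4 matrix of interaction weights; rows are the
regulated genes A, B, C and columns the regulators M, A, B, C, with M the
morphogen), three diffusion rates `D` and three product half-lives `phl`:

* weights lie in [−10, 10]: negative = repression, positive = activation,
  zero = no interaction; the sign pattern of `W` is the network
  **topology**;
* `D` in [0, 0.1]; `phl` in [5, 50], converted to a first-order decay rate
  `delta = ln(2)/phl` (the physically standard half-life relation; a
  literal `delta = log2(phl)` mode is kept behind
  `model_params(delta_mode = "log2_phl")` for comparison — it makes decay
  *increase* with half-life, which is why it is not the default).

The field is `N = 30` cells with a static exponential morphogen profile
`M_n = A0 · exp(−(n/N)/h)`, `A0 = 1`, `h = 0.4`; cell `n` sits at relative
position `n/N`, so the first cell receives `A0 · exp(−(1/N)/h)`, not `A0`.
Morphogen dynamics are out of scope; the gradient is an input, not a state
variable.

Each gene's concentration obeys

    d[G]_i,n/dt = g(u_i,n) + D_i ([G]_i,n−1 − [G]_i,n + [G]_i,n+1 − [G]_i,n)
                  − delta_i [G]_i,n

with regulatory input `u_i = Σ_j w_ij [G]_j + w_iM M_n` and the sigmoid
production rate `g(u) = 1/(1 + exp(a − b·u))`, `a = b = 5` (activation
threshold `a/b = 1`). Boundaries are zero-flux: the missing-neighbour term
is simply dropped in cells 1 and N, the usual convention for a closed
tissue. All concentrations start at 0.1, and the phenotype is the state
after 500 time units.

```{r}
g <- make_reference_i3ffl()
series <- integrate_grn(g)
round(series_slice(series, 500)[, c(1, 8, 15, 22, 30)], 3)
```

### Numerical choices

Integration uses deSolve's `lsoda` (adaptive step, automatic switching
between stiff and non-stiff modes) with absolute and relative tolerance
1e−6. The solver identity is deliberately unimportant: correctness is
pinned by an *independent* fixed-step Euler integrator (`euler_integrate`,
`dt = 0.001`, its own compiled loop) which must agree with the adaptive
solve to 1e−3 maximum absolute difference at `t = 500` — a contract the
test suite enforces on seeded random genotypes. `lsoda` was preferred over
a plain explicit Runge–Kutta because randomly drawn genotypes are
occasionally stiff; an explicit method either blows up or crawls there.
A solve that still fails (non-finite state, step-limit hit) is *flagged*,
and the genotype scores fitness 0 rather than aborting a search chain.
Concentrations may undershoot zero at solver-noise level; scoring clamps
undershoot up to 1e−3 and treats anything worse as a failed solve.
Spatial variance below 1e−12 is treated as exactly zero so that uniform
phenotypes score an exact fitness of 0.

## Fitness

Three filters are combined:

* `S` — steady-state residual: mean squared change per gene and cell
  between `t = 250` and `t = 500`; the trajectory counts as settled when
  `S < 0.001` (strict);
* `P` — spatial heterogeneity: mean squared deviation of each gene from
  its own spatial mean at `t = 500`;
* `PF_eff = 1 − D_obs/D_max` — pattern match: the profile of the output
  gene is normalized by its field maximum, binned into integers 1–10 by
  `max(1, ceiling(10·v/v_max))`, and compared to the ideal stripe (10 in
  cells 11–20, 1 elsewhere) by Manhattan distance; `D_max = 9N = 270` is
  the analytically worst case. An all-zero profile has no meaningful
  normalization and scores 0 directly.

The quality transforms `Q1(P) = P^10/(P^10 + 0.1^10)` (sharp switch at
P = 0.1, rewarding heterogeneous fields) and
`Q2(S) = 0.1²/(S² + 0.1²)` (penalizing unsettled trajectories) give the
composite fitness `F = PF_eff · Q1 · Q2 ∈ [0, 1]`.

The study speaks of *the* output gene but accepts networks striped in *at
least one* gene, so `fitness_score()` computes `PF_eff` for all three
genes and scores the best one, recording which (`output_gene`). For fields
other than 30 cells the target band generalizes to the middle third.

```{r}
fitness_score(series)
```

## Design-space search

Each chain starts from a random genotype (each weight zero with
probability 0.25, the package's choice where the original distribution is
unspecified — it lets searches approach topologies from both the gain and
the loss side; exposed as `search_config(sparsity = )`). One mutation is
drawn per step: a half-life redraw (p = 0.15), a diffusion redraw
(p = 0.15), or a weight mutation (p = 0.7) which zeroes the entry with
probability 0.2 and otherwise redraws it on [−10, 10]. Redraws use the
full prior range; the morphogen column mutates like any other weight —
multi-input designs are the point. A proposal is accepted iff its fitness
is **greater than or equal to** the current one, so accepted-fitness
traces are non-decreasing and fitness-neutral drift across topologies is
possible.

Whenever the chain's current genotype scores `F ≥ 0.95` and its canonical
topology has not been saved earlier in that chain, genotype and topology
are recorded. (The source description — a topology "not sampled in
previous steps" — is ambiguous about sub-threshold visits; blocking on
*any* earlier visit would mostly block the very class a chain converges
to, so novelty is tracked against the saved set. Both readings were
compared empirically and the choice barely affects yield.) Chains are
independent; per-chain seeds derive from the master seed, and pooled saves
are classified together.

## Topology algebra

Two topologies are isomorphic iff some relabeling of the three genes maps
one sign matrix onto the other (simultaneous row and column permutation;
the morphogen column never moves). `canonicalize()` returns the
lexicographically minimal matrix over the 6 permutations; classification,
abundance counts and class numbering (decreasing abundance, ties broken by
canonical string) follow. The orbit Hamming distance — the minimum over
isomorphs of the entrywise sign difference — makes gained/removed
interactions distance 1 and sign flips distance 2; the **neutral network**
joins classes at distance 1 (`k = 2` adds two-step neighbours). Graph
descriptors, Poisson degree-fit, abundance–degree rank correlation and
greedy-modularity communities are computed with igraph.

The motif census matches named signed subgraphs (the eight FFL types with
the morphogen as apex, autoregulation, feedback loops by length and loop
sign, mutual inhibition/activation, opposing-gradients,
overlapping-domains, and a Gierer–Meinhardt-like core) by injective role
assignment with extra edges allowed — "contains the subgraph" semantics,
which is also what subgraph-level robustness averages over. In the I3-FFL,
the motif anchoring this literature, the morphogen activates an
intermediate gene that activates the target while the morphogen directly
represses the target; the band forms where indirect activation beats
direct repression. The catalog of motifs is an ordinary named list and can
be extended by the user.

`complexity_index()` implements the degree-based information index
`Σ a_i log2 a_i` over the four nodes (morphogen included, self-loops
counting 2) — the convention that reproduces the magnitude of the
published mean (~39) for graphs of this size.

## Robustness, diffusion, field size

* **Parameter robustness**: each nonzero weight of a class representative
  (the member closest to the class mean configuration when the class has
  ≥3 members, otherwise the fittest member) is scaled ×1.2 and ×0.8 one at
  a time — values are clipped back into [−10, 10], keeping variants inside
  the declared genotype space; the class is robust if at least half the
  variants keep `F ≥ 0.95`. The morphogen column is included by default
  (configurable), consistent with treating it as a mutable input.
* **Environmental robustness**: `A0`, `h` or the initial concentrations
  are drawn from a Normal with CV 30% (truncated at 1e−6 so no negative
  parameter reaches the solver), one parameter class per assay, 100 assays
  by default; initial concentrations are drawn per gene independently.
* **Diffusion independence**: a genotype is diffusion independent if it
  still scores `F ≥ 0.9` with `D = 0` (the source states no numeric
  cutoff; 0.9 — "still produces the stripe" — is the package default and
  configurable).
* **Field-size scaling**: for `N ∈ {10, 20, 40, 50}` the gradient is
  re-anchored so the first- and last-cell morphogen concentrations equal
  the 30-cell values (closed form
  `h' = (1 − 1/N)/ln(M_first/M_last)`, `A0' = M_last·e^{1/h'}`, exact to
  1e−9), the target band is the middle third, and per-genotype fitness
  vectors are summarized by PCA.

## Phenotype and profile clustering

Spatiotemporal phenotypes are 3×26×30 tensors (samples every 10 time units
from 0 to 250). Pairwise distances are Euclidean/Frobenius — the source
does not name its metric, and the Frobenius norm is the standard default
for dense numeric arrays — and trees come from neighbor joining (ape),
which recovers additive matrices exactly. Topology classes are likewise
clustered by Hamming distances between their binary motif-presence
vectors.

## What the generator emulates — and what it does not

All inputs are generated internally: random genotypes over the stated
parameter ranges, random sign matrices for the entropy null (per-entry
zero probability 0.2, signs equiprobable — an explicit approximation,
since the original null generator is unspecified), and tuned reference
designs (`make_reference_i3ffl()`, `make_two_gene_gm()`,
`make_diffusion_reliant()`) found once by seeded hill climbs restricted to
their sign classes and frozen as constants, so tests verify deterministic
genotypes rather than re-tuning. The synthetic data emulate the study's
own inputs faithfully — the study *is* simulation-based — but none of it
captures real regulatory biology: no transcription/translation delay, no
stochasticity, no growth, a static gradient. Passing tests certify the
computational pipeline, not any claim about real tissues.

## Problem sizes and reduced-scale behaviour

The full-scale study (500 chains × 50000 steps, ~25 million ODE solves)
yields thousands of saved designs in hundreds of classes. The package's
default analyses and its acceptance checks run a *reduced* study —
16 chains × 8000 steps — which one CPU completes in minutes. Reduced runs
are qualitatively different in ways worth understanding:

* few chains cross the 0.95 save threshold at all, and a single
  high-fitness chain can contribute most of the saved classes by neutral
  drift, so saved classes are strongly correlated within chains;
* with few saving chains there is almost no cross-chain duplication of
  classes, so the abundance distribution is nearly uniform; the entropy
  gap between observed catalogs and the selection-free null — clear at
  full scale — need not be visible, and motif prevalences can sit far
  from their full-scale values;
* headline counts of the full-scale study (thousands saved, hundreds of
  classes, a dominant 95-member class) are therefore reference points,
  not reproduction targets, at this scale.

## Known limitations

* The degradation-rate formula and the exact entropy-null generator are
  ambiguous in the source; both choices here are explicit and switchable.
* Community structure uses greedy modularity; the original clustering
  method is unknown, so only qualitative structure is claimed.
* Motif-catalog size is configurable; the original's own figure and table
  disagree on whether it has 17 or 19 subgraphs.
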