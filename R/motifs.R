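#' Built-in catalog of signed subgraph motifs
#'
#' Named signed subgraphs relevant to morphogen interpretation: the eight
#' coherent/incoherent feed-forward loop (FFL) types with the morphogen as
#' apex, positive/negative autoregulation, 2- and 3-node feedback loops by
#' loop sign, mutual inhibition (bistable switch) and mutual activation,
#' the opposing-gradients and overlapping-domains mechanisms, and a
#' Gierer-Meinhardt-like activator-inhibitor core.
#'
#' Each motif is an edge list over abstract roles: `"M"` is the morphogen
#' (always mapped to the morphogen node) and `"X"`, `"Y"`, `"Z"` are gene
#' slots filled injectively. Cycle-type motifs are instead specified by loop
#' length and loop sign. FFL sign conventions, with `s1 = M -> Y`,
#' `s2 = Y -> Z`, `s3 = M -> Z`: coherent types have `s1 * s2 == s3`
#' (C1 `+,+,+`; C2 `-,-,+`; C3 `+,-,-`; C4 `-,+,-`) and incoherent types the
#' opposite (I1 `+,-,+`; I2 `-,+,+`; I3 `+,+,-`; I4 `-,-,-`). In the I3-FFL
#' the morphogen indirectly activates the target through the intermediate
#' while directly repressing it.
#'
#' @return named list of motif definitions (class `motif_catalog`).
#' @export
default_motif_catalog <- function() {
  ffl <- function(s1, s2, s3) {
    list(type = "edges",
         edges = data.frame(from = c("M", "Y", "M"), to = c("Y", "Z", "Z"),
                            sign = c(s1, s2, s3)))
  }
  edges_motif <- function(from, to, sign) {
    list(type = "edges", edges = data.frame(from = from, to = to, sign = sign))
  }
  cyc <- function(len, sign) list(type = "cycle", length = len, sign = sign)
  m <- list(
    ffl_c1 = ffl(1, 1, 1),   ffl_c2 = ffl(-1, -1, 1),
    ffl_c3 = ffl(1, -1, -1), ffl_c4 = ffl(-1, 1, -1),
    ffl_i1 = ffl(1, -1, 1),  ffl_i2 = ffl(-1, 1, 1),
    ffl_i3 = ffl(1, 1, -1),  ffl_i4 = ffl(-1, -1, -1),
    autoreg_pos = cyc(1, 1),
    autoreg_neg = cyc(1, -1),
    fbl2_pos = cyc(2, 1),
    fbl2_neg = cyc(2, -1),
    fbl3_pos = cyc(3, 1),
    fbl3_neg = cyc(3, -1),
    bistable = edges_motif(c("X", "Y"), c("Y", "X"), c(-1, -1)),
    mutual_activation = edges_motif(c("X", "Y"), c("Y", "X"), c(1, 1)),
    opposing_gradients = edges_motif(c("M", "M", "X", "Y"),
                                     c("X", "Y", "Z", "Z"),
                                     c(1, -1, -1, -1)),
    overlapping_domains = edges_motif(c("M", "Y", "M", "Z"),
                                      c("Y", "Z", "Z", "Z"),
                                      c(1, 1, -1, 1)),
    gm_core = edges_motif(c("Z", "Z", "Y"), c("Z", "Y", "Z"), c(1, 1, -1))
  )
  structure(m, class = "motif_catalog")
}

# sign of edge u -> v in a sign-topology matrix; nodes "M","A","B","C"
.edge_sign <- function(topo, from, to) {
  topo[cbind(match(to, c("A", "B", "C")), match(from, c("M", "A", "B", "C")))]
}

# sign products of all simple directed cycles among the gene nodes
# (lengths 1, 2, 3), self-loops included as length-1 cycles
cycle_sign_products <- function(topo) {
  s <- signify(topo)
  a <- s[, 2:4]  # 3x3 gene adjacency: a[i, j] = sign of edge j -> i
  out <- list()
  for (i in 1:3) if (a[i, i] != 0)
    out[[length(out) + 1L]] <- c(length = 1, sign = a[i, i])
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    if (a[j, i] != 0 && a[i, j] != 0)
      out[[length(out) + 1L]] <- c(length = 2, sign = a[j, i] * a[i, j])
  }
  for (ord in list(c(1, 2, 3), c(1, 3, 2))) {
    e1 <- a[ord[2], ord[1]]; e2 <- a[ord[3], ord[2]]; e3 <- a[ord[1], ord[3]]
    if (e1 != 0 && e2 != 0 && e3 != 0)
      out[[length(out) + 1L]] <- c(length = 3, sign = e1 * e2 * e3)
  }
  if (length(out) == 0) matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("length", "sign")))
  else do.call(rbind, out)
}

# injective assignments of motif gene roles to the genes A, B, C
.role_assignments <- function(roles) {
  genes <- c("A", "B", "C")
  if (length(roles) == 1) return(lapply(genes, function(g) stats::setNames(g, roles)))
  if (length(roles) == 2) {
    combos <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
    return(lapply(combos, function(ix) stats::setNames(genes[ix], roles)))
  }
  lapply(.gene_perms, function(p) stats::setNames(genes[p], roles))
}

#' Census of motifs present in a sign topology
#'
#' A motif is present iff some injective mapping of its gene roles onto the
#' three genes (the morphogen role always maps to the morphogen) matches
#' every motif edge's sign; additional edges in the network are allowed
#' (non-induced matching). Cycle-type motifs are present iff a directed
#' cycle of the stated length and loop sign exists among the genes.
#'
#' @param topo a sign-topology matrix (or genotype).
#' @param catalog a motif catalog, by default [default_motif_catalog()].
#' @return named logical vector, one entry per motif, plus the derived flags
#'   `multi_input` (at least two genes receive the morphogen) and
#'   `neg_feedback` / `pos_feedback` (any directed cycle with negative /
#'   positive sign product).
#' @export
motif_census <- function(topo, catalog = default_motif_catalog()) {
  s <- signify(topo)
  present <- vapply(catalog, function(m) {
    if (m$type == "cycle") {
      cy <- cycle_sign_products(s)
      return(any(cy[, "length"] == m$length & cy[, "sign"] == m$sign))
    }
    roles <- setdiff(unique(c(m$edges$from, m$edges$to)), "M")
    for (asg in .role_assignments(roles)) {
      map <- function(x) ifelse(x == "M", "M", asg[x])
      ok <- all(.edge_sign(s, map(m$edges$from), map(m$edges$to)) ==
                  m$edges$sign)
      if (ok) return(TRUE)
    }
    FALSE
  }, logical(1))
  cy <- cycle_sign_products(s)
  c(present,
    multi_input = sum(s[, 1] != 0) >= 2,
    neg_feedback = any(cy[, "sign"] == -1),
    pos_feedback = any(cy[, "sign"] == 1))
}

#' Motif-presence matrix for a topology catalog
#'
#' One row per isomorphism class, one binary column per motif (plus the
#' derived flags); the subgraph-profile matrix used for motif prevalence
#' statistics and profile-based clustering.
#'
#' @param catalog a `topology_catalog`.
#' @param motifs a motif catalog.
#' @return binary integer matrix with one row per class.
#' @export
motif_profile_matrix <- function(catalog, motifs = default_motif_catalog()) {
  if (nrow(catalog$classes) == 0) stop("empty catalog")
  profs <- t(vapply(catalog$topologies,
                    function(tp) motif_census(tp, motifs) * 1L,
                    integer(length(motifs) + 3L)))
  rownames(profs) <- catalog$classes$canonical
  profs
}
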