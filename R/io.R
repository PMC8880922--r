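#' Read and write genotypes as JSON
#'
#' Genotypes are stored as a JSON array of objects with fields `W` (12
#' row-major weights), `D`, `phl`, and optional `id` and `fitness`; the
#' round trip is exact (doubles serialized at full precision).
#'
#' @param genotypes list of `grn_genotype`s (or a single one).
#' @param path output file.
#' @export
write_genotype_json <- function(genotypes, path) {
  if (inherits(genotypes, "grn_genotype")) genotypes <- list(genotypes)
  recs <- lapply(genotypes, function(g) {
    r <- list(W = as.numeric(t(g$W)), D = g$D, phl = g$phl)
    if (!is.null(g$id)) r$id <- g$id
    if (!is.null(g$fitness)) r$fitness <- g$fitness
    r
  })
  jsonlite::write_json(recs, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_genotype_json
#' @return `read_genotype_json` returns a list of `grn_genotype`s.
#' @export
read_genotype_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    g <- genotype(W = matrix(as.numeric(r$W), 3, 4, byrow = TRUE),
                  D = as.numeric(r$D), phl = as.numeric(r$phl),
                  id = r$id)
    if (!is.null(r$fitness)) g$fitness <- as.numeric(r$fitness)
    g
  })
}

#' Export a time series as long-format CSV
#'
#' Columns `gene`, `time`, `cell`, `concentration`.
#'
#' @param series a `grn_series`.
#' @param path output file.
#' @export
write_phenotype_csv <- function(series, path) {
  dims <- dim(series$conc)
  df <- expand.grid(gene = c("A", "B", "C"), time = series$times,
                    cell = seq_len(dims[3]), stringsAsFactors = FALSE)
  df$concentration <- as.vector(series$conc)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a topology catalog as CSV
#'
#' Columns: `class_id`, `canonical` (12-character `-0+` string),
#' `abundance`, `p`, `complexity`, plus one 0/1 column per motif flag.
#'
#' @param catalog a `topology_catalog`.
#' @param path output file.
#' @param motifs motif catalog used for the flag columns (NULL to omit).
#' @export
write_catalog_csv <- function(catalog, path,
                              motifs = default_motif_catalog()) {
  df <- catalog$classes
  df$complexity <- vapply(catalog$topologies, complexity_index, numeric(1))
  if (!is.null(motifs) && nrow(df) > 0) {
    profs <- motif_profile_matrix(catalog, motifs)
    df <- cbind(df, as.data.frame(profs, row.names = NULL))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a catalog CSV back into a `topology_catalog`
#'
#' Reconstructs classes (without member genotypes) from the `canonical` and
#' `abundance` columns.
#'
#' @param path a CSV written by [write_catalog_csv()].
#' @return a `topology_catalog` (members hold per-class placeholder
#'   indices).
#' @export
read_catalog_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  n <- sum(df$abundance)
  idx <- 0L
  members <- lapply(df$abundance, function(k) {
    out <- idx + seq_len(k)
    idx <<- idx + k
    out
  })
  structure(list(
    classes = data.frame(class_id = df$class_id, canonical = df$canonical,
                         abundance = as.integer(df$abundance),
                         p = df$abundance / n, row.names = NULL),
    members = members,
    topologies = lapply(df$canonical, parse_topology)
  ), class = "topology_catalog")
}

#' Export a metagraph
#'
#' Writes GraphML (full attributes, re-importable with
#' [igraph::read_graph()]) and a TSV edge list plus a TSV node-attribute
#' table.
#'
#' @param graph an `igraph` graph with `name`, `class_id`, `abundance`
#'   vertex attributes.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "metagraph").
#' @return invisible character vector of the files written.
#' @export
write_metagraph <- function(graph, dir, prefix = "metagraph") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gml <- file.path(dir, paste0(prefix, ".graphml"))
  igraph::write_graph(graph, gml, format = "graphml")
  el <- igraph::as_edgelist(graph, names = TRUE)
  edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), edges,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  nodes <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  utils::write.table(
    data.frame(name = igraph::V(graph)$name,
               class_id = igraph::V(graph)$class_id,
               abundance = igraph::V(graph)$abundance,
               degree = igraph::degree(graph)),
    nodes, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(gml, edges, nodes))
}

#' Read and write flat key-value configuration files
#'
#' Plain YAML mappings holding the simulation settings (`N`, `A0`, `h`,
#' `a`, `b`, `t_max`, `init_conc`, `delta_mode`, `rtol`, `atol`) and any
#' search settings; unknown keys are preserved.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Assemble field and model settings from a configuration list
#'
#' @param config named list as from [read_config()]; missing keys fall back
#'   to the package defaults.
#' @return list with `field` ([field_config()]) and `params`
#'   ([model_params()]).
#' @export
config_to_settings <- function(config = list()) {
  pick <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  field <- field_config(N = pick("N", 30), A0 = pick("A0", 1),
                        h = pick("h", 0.4),
                        init_conc = pick("init_conc", 0.1))
  params <- model_params(a = pick("a", 5), b = pick("b", 5),
                         t_max = pick("t_max", 500),
                         rtol = pick("rtol", 1e-6), atol = pick("atol", 1e-6),
                         delta_mode = pick("delta_mode", "ln2_over_phl"))
  list(field = field, params = params)
}
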