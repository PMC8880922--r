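#' Run the full analysis pipeline
#'
#' Orchestrates search, classification, metagraph construction, robustness
#' scoring, phenotype/subgraph clustering, and the field-size scan, writing
#' all artifacts and a run manifest to `out_dir`. Every stage degrades
#' gracefully when the catalog is too small (e.g. zero or one saved class)
#' and records what was skipped in the manifest.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed for the whole run.
#' @param config a [search_config()] controlling the exploration scale.
#' @param field a [field_config()].
#' @param params a [model_params()].
#' @param max_robustness_classes robustness is scored for at most this many
#'   of the most abundant classes (it re-simulates many variants).
#' @param max_clustering_genotypes cap on genotypes entering phenotype
#'   clustering.
#' @param progress print stage progress.
#' @return invisible list with all in-memory results (`search`, `catalog`,
#'   `metagraph`, `descriptors`, `robustness`, `clustering`, `fieldscan`,
#'   `manifest`).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         config = search_config(n_chains = 10,
                                                steps_per_chain = 2000,
                                                seed = seed),
                         field = field_config(), params = model_params(),
                         max_robustness_classes = 10,
                         max_clustering_genotypes = 40,
                         progress = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- seed
  say <- function(...) if (progress) message(...)

  say("search: ", config$n_chains, " chains x ", config$steps_per_chain,
      " steps")
  res <- run_search(config, field, params, progress = progress)
  catalog <- res$catalog
  write_genotype_json(res$genotypes, file.path(out_dir, "genotypes.json"))
  write_catalog_csv(catalog, file.path(out_dir, "catalog.csv"))

  skipped <- character()
  descriptors <- NULL
  mg <- NULL
  if (nrow(catalog$classes) >= 2) {
    say("metagraph")
    mg <- build_metagraph(catalog, k = 1)
    descriptors <- metagraph_descriptors(mg)
    write_metagraph(mg, out_dir)
  } else skipped <- c(skipped, "metagraph")

  robustness <- NULL
  if (nrow(catalog$classes) >= 1) {
    say("robustness")
    top <- utils::head(seq_len(nrow(catalog$classes)),
                       max_robustness_classes)
    robustness <- data.frame(
      class_id = top,
      score = vapply(top, function(ci) {
        members <- res$genotypes[catalog$members[[ci]]]
        robustness_score(members, field, params)$score
      }, numeric(1)))
    robustness$robust <- robustness$score >= 0.5
    utils::write.csv(robustness, file.path(out_dir, "robustness.csv"),
                     row.names = FALSE)
  } else skipped <- c(skipped, "robustness")

  clustering <- NULL
  if (length(res$genotypes) >= 3) {
    say("clustering")
    sel <- utils::head(seq_along(res$genotypes), max_clustering_genotypes)
    clustering <- phenotype_clustering(res$genotypes[sel], field, params)
    ape::write.tree(clustering$tree,
                    file.path(out_dir, "phenotype_tree.nwk"))
    if (nrow(catalog$classes) >= 3) {
      sub <- subgraph_profile_clustering(catalog)
      ape::write.tree(sub$tree, file.path(out_dir, "subgraph_tree.nwk"))
    }
  } else skipped <- c(skipped, "clustering")

  fieldscan <- NULL
  if (length(res$genotypes) >= 1) {
    say("field-size scan")
    sel <- utils::head(seq_along(res$genotypes), max_clustering_genotypes)
    fieldscan <- field_size_scan(res$genotypes[sel], base = field,
                                 params = params)
    utils::write.csv(as.data.frame(fieldscan$fitness),
                     file.path(out_dir, "fieldsize_fitness.csv"),
                     row.names = FALSE)
  } else skipped <- c(skipped, "fieldsize")

  manifest <- list(
    seed = seed,
    n_chains = config$n_chains, steps_per_chain = config$steps_per_chain,
    save_threshold = config$save_threshold,
    field = unclass(field), params = unclass(params),
    n_saved = length(res$genotypes), n_classes = nrow(catalog$classes),
    skipped_stages = as.list(skipped),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(search = res, catalog = catalog, metagraph = mg,
                 descriptors = descriptors, robustness = robustness,
                 clustering = clustering, fieldscan = fieldscan,
                 manifest = manifest))
}
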