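#' Default pipeline configuration
#'
#' Every decision exposed by the individual stages is representable here;
#' the defaults reproduce the standard settings (alpha = 0.05, Louvain
#' resolution 1, candidate-pair FDR family).
#'
#' @param associations,categories Paths to the association table and the
#'   URI -> category map (TSV).
#' @param ancestry Optional path to the ancestry annotation table.
#' @param focal_pubmed_ids Optional character vector (or path to a one-id-
#'   per-line file) of focal-source PubMed ids.
#' @param out_dir Output directory.
#' @param alpha,fdr_family,keep_isolates Passed to [build_network()].
#' @param column_map Column mapping for the association table.
#' @param louvain_seed,resolution Passed to [detect_communities()].
#' @param n_null Null samples for [community_significance()]; 0 skips the
#'   significance stage.
#' @param european_mode Passed to [build_stratified_networks()].
#' @param corr_threshold Threshold for the neighborhood-correlation summary.
#' @return A named configuration list.
#' @export
pipeline_config <- function(associations, categories, out_dir,
                            ancestry = NULL, focal_pubmed_ids = NULL,
                            alpha = 0.05, fdr_family = "candidates",
                            keep_isolates = FALSE,
                            column_map = default_column_map(),
                            louvain_seed = 0L, resolution = 1,
                            n_null = 1000L, european_mode = "any",
                            novel_mode = "common_threshold",
                            corr_threshold = 0.4) {
  as.list(environment())
}

stage_msg <- function(...) message("[phenonet] ", ...)

#' Run the full phenotype-network pipeline
#'
#' Stages: parse -> category mapping -> trait filter -> index -> network ->
#' communities (+ significance) -> summaries; then, when configured, the
#' focal-source differential subnetwork and the ancestry-stratified
#' comparison. All outputs are written under `config$out_dir` together with
#' a provenance JSON (config echo, input checksums, stage counts, seeds)
#' that fully determines the run.
#'
#' @param config A [pipeline_config()] list, or path to a YAML file with the
#'   same fields.
#' @return Invisibly, a list with the in-memory stage results
#'   (`records`, `traits`, `index`, `network`, `partition`, ...).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    config$column_map <- if (is.null(config$column_map)) default_column_map()
      else unlist(config$column_map)
  }
  defaults <- list(alpha = 0.05, fdr_family = "candidates",
                   keep_isolates = FALSE, louvain_seed = 0L, resolution = 1,
                   n_null = 1000L, european_mode = "any",
                   novel_mode = "common_threshold", corr_threshold = 0.4,
                   ancestry = NULL, focal_pubmed_ids = NULL,
                   column_map = default_column_map())
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("associations", "categories", "out_dir")) {
    if (is.null(config[[nm]])) stop("pipeline config is missing `", nm, "`")
  }
  for (nm in c("associations", "categories")) {
    if (!file.exists(config[[nm]])) {
      stop("input file for `", nm, "` not found: ", config[[nm]])
    }
  }
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  prov <- list(config = config[setdiff(names(config), "column_map")],
               column_map = as.list(config$column_map),
               inputs = list(), counts = list())
  t0 <- proc.time()[["elapsed"]]

  stage_msg("parsing associations")
  prov$inputs$associations <- unname(tools::md5sum(config$associations))
  parsed <- parse_association_table(config$associations,
                                    column_map = config$column_map)
  records <- parsed$records
  prov$counts$records <- nrow(records)
  prov$counts$dropped <- as.list(parsed$dropped)

  stage_msg("mapping trait categories and filtering")
  prov$inputs$categories <- unname(tools::md5sum(config$categories))
  category_map <- utils::read.delim(config$categories, check.names = FALSE,
                                    stringsAsFactors = FALSE)
  traits <- map_trait_categories(records, category_map)
  filt <- filter_traits(traits)
  prov$counts$traits_total <- nrow(traits)
  prov$counts$traits_removed <- nrow(filt$removed)

  stage_msg("building index and network")
  index <- build_index(records, filt$retained$trait_label)
  network <- build_network(index, alpha = config$alpha,
                           fdr_family = config$fdr_family,
                           traits = filt$retained,
                           keep_isolates = config$keep_isolates)
  prov$counts <- c(prov$counts, network$provenance[
    c("n_variants", "m", "n_candidate_pairs", "n_edges", "n_traits_indexed",
      "n_isolates")])
  write_edge_table(network$edges, file.path(out, "edges.tsv"))
  write_network_graphml(network, file.path(out, "network.graphml"))

  stage_msg("communities and summaries")
  partition <- NULL
  significance <- NULL
  if (nrow(network$edges) > 0) {
    partition <- detect_communities(network, resolution = config$resolution,
                                    seed = config$louvain_seed)
    prov$counts$n_communities <- nrow(partition$communities)
    prov$counts$modularity <- partition$modularity
    memb_df <- data.frame(trait = names(partition$membership),
                          community = unname(partition$membership))
    memb_df <- memb_df[order(memb_df$trait, method = "radix"), ]
    utils::write.table(memb_df, file.path(out, "communities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (config$n_null > 0) {
      significance <- community_significance(network, partition,
                                             n_null = config$n_null,
                                             seed = config$louvain_seed)
      utils::write.table(significance,
                         file.path(out, "community_significance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summ <- node_summary(network, index)
    utils::write.table(summ, file.path(out, "node_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dd <- log_binned_degree_distribution(degree_sequence(network)[
      degree_sequence(network) > 0])
    utils::write.table(dd, file.path(out, "degree_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    vec <- variant_edge_counts(network, records)
    utils::write.table(vec, file.path(out, "variant_edge_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  differential <- NULL
  if (!is.null(config$focal_pubmed_ids)) {
    stage_msg("focal-source differential subnetwork")
    ids <- config$focal_pubmed_ids
    if (length(ids) == 1L && file.exists(ids)) ids <- readLines(ids)
    src <- split_by_source(records, ids)
    if (config$novel_mode == "intersect_only") {
      differential <- novel_edges(network, flagged_records = src$flagged,
                                  mode = "intersect_only")
    } else {
      common <- config$novel_mode == "common_threshold"
      reduced_net <- build_network(
        build_index(src$reduced, filt$retained$trait_label),
        alpha = config$alpha, fdr_family = config$fdr_family,
        traits = filt$retained, keep_isolates = config$keep_isolates,
        universe_size = if (common) network$provenance$n_variants else NULL,
        p_threshold_override = if (common) {
          if (nrow(network$edges)) max(network$edges$p_value) else 0
        } else NULL)
      differential <- novel_edges(network, reduced_net, src$flagged)
    }
    prov$counts$n_novel_edges <- nrow(differential$novel_edges)
    prov$counts$n_novel_nodes <- length(differential$novel_nodes)
    write_edge_table(differential$novel_edges, file.path(out, "novel_edges.tsv"))
  }

  strata <- NULL
  strat_corr <- NULL
  if (!is.null(config$ancestry)) {
    stage_msg("ancestry-stratified networks")
    prov$inputs$ancestry <- unname(tools::md5sum(config$ancestry))
    ann <- parse_ancestry_table(config$ancestry)
    flagged <- stratum_flags(records, ann)
    strata <- build_stratified_networks(flagged, filt$retained$trait_label,
                                        alpha = config$alpha,
                                        fdr_family = config$fdr_family,
                                        traits = filt$retained,
                                        european_mode = config$european_mode)
    prov$counts$n_edges_european <- nrow(strata$european$edges)
    prov$counts$n_edges_non_european <- nrow(strata$non_european$edges)
    write_edge_table(strata$european$edges, file.path(out, "edges_european.tsv"))
    write_edge_table(strata$non_european$edges,
                     file.path(out, "edges_non_european.tsv"))
    vp <- neighborhood_vectors(strata$european, strata$non_european)
    if (length(vp)) {
      strat_corr <- neighborhood_correlation(vp,
                                             threshold = config$corr_threshold)
      utils::write.table(strat_corr$correlations,
                         file.path(out, "neighborhood_correlations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(strat_corr$histogram,
                         file.path(out, "correlation_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      prov$counts$frac_corr_below_threshold <- strat_corr$frac_below_threshold
    }
  }

  stage_msg(sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(records = records, traits = traits, filtered = filt,
                 index = index, network = network, partition = partition,
                 significance = significance, differential = differential,
                 strata = strata, stratified_correlation = strat_corr,
                 provenance = prov))
}
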