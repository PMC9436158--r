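# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# Minimal association records from named variant sets (one record per trait).
records_from_sets <- function(sets, pubmed = NULL, p_value = 1e-8) {
  traits <- names(sets)
  if (is.null(pubmed)) pubmed <- sprintf("pm%03d", seq_along(traits))
  df <- data.frame(
    study_accession = sprintf("GCST%03d", seq_along(traits)),
    pubmed_id = pubmed,
    trait_label = traits,
    mapped_gene = "",
    p_value = p_value,
    stringsAsFactors = FALSE)
  df$efo_uris <- I(as.list(sprintf("uri:%s", traits)))
  df$variant_ids <- I(unname(lapply(sets, unique)))
  df
}

network_from_sets <- function(sets, alpha = 0.05, ...) {
  build_network(build_index(records_from_sets(sets)), alpha = alpha, ...)
}

# The 4-trait worked example: two candidate pairs over a 5-variant universe.
toy_sets <- function() {
  list(T1 = c("v1", "v2", "v3"),
       T2 = c("v2", "v3", "v4"),
       T3 = "v9",
       T4 = "v9")
}

# Hand-assemble a phenotype_network from an edge list (graph-topology tests
# that do not care about the statistical columns).
pn_from_edges <- function(edge_pairs, nodes = NULL) {
  if (length(edge_pairs)) {
    a <- vapply(edge_pairs, `[`, "", 1)
    b <- vapply(edge_pairs, `[`, "", 2)
    edges <- data.frame(trait_a = pmin(a, b), trait_b = pmax(a, b),
                        shared_count = 1L, union_count = 2L, jaccard = 0.5,
                        p_value = 0.01, q_value = 0.01,
                        stringsAsFactors = FALSE)
    edges$shared_variants <- I(rep(list("v1"), nrow(edges)))
    edges <- edges[order(edges$trait_a, edges$trait_b, method = "radix"), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(trait_a = character(0), trait_b = character(0),
                        shared_count = integer(0), union_count = integer(0),
                        jaccard = numeric(0), p_value = numeric(0),
                        q_value = numeric(0), stringsAsFactors = FALSE)
    edges$shared_variants <- I(list())
  }
  if (is.null(nodes)) nodes <- sort(unique(c(edges$trait_a, edges$trait_b)))
  net <- list(nodes = data.frame(trait = nodes, stringsAsFactors = FALSE),
              edges = edges,
              provenance = list(alpha = 0.05, fdr_family = "candidates",
                                n_variants = 2L, m = nrow(edges),
                                keep_isolates = TRUE))
  class(net) <- "phenotype_network"
  net
}

# A modest random network reused by tests that only need "some network".
prepared_network_cache <- local({
  set.seed(555)
  vars <- sprintf("rs%03d", 1:40)
  sets <- lapply(1:15, function(i) sample(vars, sample(3:8, 1)))
  names(sets) <- sprintf("T%02d", 1:15)
  list(sets = sets, net = network_from_sets(sets, alpha = 1))
})

# Generate a synthetic catalog, write it out, and run it through parsing
# and filtering; returns the pieces most tests need.
prepared_catalog <- function(config = synthetic_config(), dir = tempfile()) {
  cat0 <- generate_catalog(config)
  write_catalog(cat0, dir)
  parsed <- parse_association_table(file.path(dir, "associations.tsv"))
  category_map <- utils::read.delim(file.path(dir, "category_map.tsv"),
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE)
  traits <- map_trait_categories(parsed$records, category_map)
  filt <- filter_traits(traits)
  list(catalog = cat0, dir = dir, parsed = parsed, records = parsed$records,
       traits = traits, filtered = filt)
}
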