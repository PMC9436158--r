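#' Default column mapping for GWAS-Catalog association tables
#'
#' Maps the logical columns the pipeline needs onto the header names used by
#' the GWAS Catalog v1.0.2 association download. Synthetic or simplified
#' tables can supply their own mapping to [parse_association_table()].
#'
#' @return Named character vector: logical name -> column header.
#' @export
default_column_map <- function() {
  c(
    study   = "STUDY ACCESSION",
    pubmed  = "PUBMEDID",
    trait   = "MAPPED_TRAIT",
    efo_uri = "MAPPED_TRAIT_URI",
    snps    = "SNPS",
    gene    = "MAPPED_GENE",
    p_value = "P-VALUE"
  )
}

#' Parse a variant identifier field
#'
#' The catalog packs several variants into one cell using `"; "`, `","`, or
#' the haplotype marker `" x "`. Tokens are trimmed, the `rs` prefix is
#' case-normalised to lowercase, and duplicates are removed preserving first
#' occurrence. Non-rsID tokens (e.g. chr:pos identifiers) are kept verbatim.
#'
#' @param raw A single character string (the raw SNPS cell).
#' @return Character vector of variant identifiers; empty if nothing parseable.
#' @export
parse_snp_field <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L) {
    stop("`raw` must be a single character string")
  }
  if (is.na(raw)) return(character(0))
  toks <- strsplit(raw, "\\s*;\\s*|\\s*,\\s*|\\s+x\\s+")[[1]]
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  toks <- sub("^[Rr][Ss](?=[0-9])", "rs", toks, perl = TRUE)
  unique(toks)
}

#' Parse a GWAS-Catalog-style association table
#'
#' Reads a tab-delimited association table and returns one record per input
#' row. Multi-term traits are *not* expanded here (that happens during
#' category mapping); multi-variant cells are split via [parse_snp_field()].
#' Rows with an unusable variant field or p-value, or with p above
#' `p_threshold`, are dropped and counted. The catalog pre-applies the
#' p <= 1e-5 inclusion threshold, but it is re-checked on load because other
#' inputs may not.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Named character vector resolving logical columns
#'   (`study`, `pubmed`, `trait`, `efo_uri`, `snps`, `gene`, `p_value`) to
#'   header names; see [default_column_map()].
#' @param p_threshold Maximum p-value retained (default `1e-5`).
#' @return A list with elements:
#'   \describe{
#'     \item{records}{data.frame with columns `study_accession`, `pubmed_id`,
#'       `trait_label`, `efo_uris` (list), `variant_ids` (list),
#'       `mapped_gene`, `p_value`, in input order.}
#'     \item{dropped}{named integer vector of drop counts
#'       (`bad_variants`, `bad_p_value`, `over_threshold`).}
#'   }
#' @export
parse_association_table <- function(path, column_map = default_column_map(),
                                    p_threshold = 1e-5) {
  required <- c("study", "pubmed", "trait", "efo_uri", "snps", "gene", "p_value")
  missing_logical <- setdiff(required, names(column_map))
  if (length(missing_logical)) {
    stop("column_map does not define: ", paste(missing_logical, collapse = ", "))
  }
  tab <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = "character",
                      na.strings = NULL, quote = "", stringsAsFactors = FALSE),
    error = function(e) {
      warning("empty or unreadable association table: ", conditionMessage(e))
      NULL
    }
  )
  empty <- empty_association_records()
  if (is.null(tab)) {
    return(list(records = empty,
                dropped = c(bad_variants = 0L, bad_p_value = 0L, over_threshold = 0L)))
  }
  absent <- setdiff(unname(column_map[required]), names(tab))
  if (length(absent)) {
    stop("association table is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  n <- nrow(tab)
  if (n == 0L) {
    warning("association table has no data rows")
    return(list(records = empty,
                dropped = c(bad_variants = 0L, bad_p_value = 0L, over_threshold = 0L)))
  }
  variants <- lapply(tab[[column_map[["snps"]]]], parse_snp_field)
  uris <- lapply(tab[[column_map[["efo_uri"]]]], function(cell) {
    u <- trimws(strsplit(cell, ",\\s*")[[1]])
    unique(u[nzchar(u)])
  })
  p <- suppressWarnings(as.numeric(tab[[column_map[["p_value"]]]]))

  bad_var <- lengths(variants) == 0L
  bad_p <- !bad_var & (is.na(p) | p < 0 | p > 1)
  over <- !bad_var & !bad_p & p > p_threshold
  keep <- !(bad_var | bad_p | over)

  records <- data.frame(
    study_accession = tab[[column_map[["study"]]]][keep],
    pubmed_id       = tab[[column_map[["pubmed"]]]][keep],
    trait_label     = tab[[column_map[["trait"]]]][keep],
    mapped_gene     = tab[[column_map[["gene"]]]][keep],
    p_value         = p[keep],
    stringsAsFactors = FALSE
  )
  records$efo_uris <- I(uris[keep])
  records$variant_ids <- I(variants[keep])
  records <- records[, c("study_accession", "pubmed_id", "trait_label",
                         "efo_uris", "variant_ids", "mapped_gene", "p_value")]
  rownames(records) <- NULL
  list(records = records,
       dropped = c(bad_variants = sum(bad_var),
                   bad_p_value = sum(bad_p),
                   over_threshold = sum(over)))
}

empty_association_records <- function() {
  df <- data.frame(study_accession = character(0), pubmed_id = character(0),
                   trait_label = character(0), mapped_gene = character(0),
                   p_value = numeric(0), stringsAsFactors = FALSE)
  df$efo_uris <- I(list())
  df$variant_ids <- I(list())
  df[, c("study_accession", "pubmed_id", "trait_label",
         "efo_uris", "variant_ids", "mapped_gene", "p_value")]
}

#' Default ancestry roll-up map
#'
#' Collapses granular catalog ancestry labels into broad categories, e.g.
#' "Sub-Saharan African" and "African unspecified" become "African".
#' Labels not in the map pass through unchanged.
#'
#' @return Named character vector: raw label -> broad category.
#' @export
default_ancestry_rollup <- function() {
  c(
    "Sub-Saharan African" = "African",
    "African unspecified" = "African",
    "African American or Afro-Caribbean" = "African",
    "Hispanic or Latin American" = "Hispanic or Latin American",
    "East Asian" = "East Asian",
    "South Asian" = "South Asian",
    "European" = "European"
  )
}

#' Parse an ancestry annotation table
#'
#' Aggregates per-study ancestry labels across rows and applies a roll-up
#' map to collapse granular labels into broad categories. Unknown labels pass
#' through unchanged (and are reported via a message).
#'
#' @param path Path to a tab-delimited file.
#' @param rollup_map Named character vector, raw label -> broad category.
#' @param study_col,ancestry_col Column headers for study accession and
#'   ancestry label.
#' @return data.frame with columns `study_accession`, `raw_labels` (list),
#'   `rolled_labels` (list of unique broad categories).
#' @export
parse_ancestry_table <- function(path, rollup_map = default_ancestry_rollup(),
                                 study_col = "STUDY ACCESSION",
                                 ancestry_col = "BROAD ANCESTRAL CATEGORY") {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           na.strings = NULL, quote = "", stringsAsFactors = FALSE)
  for (col in c(study_col, ancestry_col)) {
    if (!col %in% names(tab)) stop("ancestry table is missing column: ", col)
  }
  lab <- trimws(tab[[ancestry_col]])
  acc <- tab[[study_col]]
  keep <- nzchar(lab)
  lab <- lab[keep]; acc <- acc[keep]
  unknown <- setdiff(unique(lab), names(rollup_map))
  if (length(unknown)) {
    message("ancestry labels passed through without roll-up: ",
            paste(unknown, collapse = ", "))
  }
  rolled <- ifelse(lab %in% names(rollup_map), rollup_map[lab], lab)
  accs <- unique(acc)
  raw_l <- split(lab, factor(acc, levels = accs))
  rol_l <- lapply(split(rolled, factor(acc, levels = accs)), unique)
  out <- data.frame(study_accession = accs, stringsAsFactors = FALSE)
  out$raw_labels <- I(unname(raw_l))
  out$rolled_labels <- I(unname(rol_l))
  out
}

#' Write and read the edge table
#'
#' The edge table has exactly the columns `trait_a`, `trait_b`,
#' `shared_count`, `union_count`, `jaccard`, `p_value`, `q_value`,
#' `shared_variants` (semicolon-joined, sorted), ordered lexicographically by
#' `trait_a` then `trait_b`. Floating-point columns are serialised with 17
#' significant digits so that a read/re-write round trip is byte-identical.
#'
#' @param edges Edge data.frame from a [build_network()] result
#'   (`network$edges`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  df <- data.frame(
    trait_a = edges$trait_a,
    trait_b = edges$trait_b,
    shared_count = edges$shared_count,
    union_count = edges$union_count,
    jaccard = sprintf("%.17g", edges$jaccard),
    p_value = sprintf("%.17g", edges$p_value),
    q_value = sprintf("%.17g", edges$q_value),
    shared_variants = vapply(edges$shared_variants,
                             function(v) paste(sort(v), collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$trait_a, df$trait_b, method = "radix"), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = c(trait_a = "character", trait_b = "character",
                                         shared_count = "integer", union_count = "integer",
                                         jaccard = "numeric", p_value = "numeric",
                                         q_value = "numeric", shared_variants = "character"))
  df$shared_variants <- I(lapply(strsplit(df$shared_variants, ";", fixed = TRUE),
                                 function(v) v[nzchar(v)]))
  df
}

#' Export / import a phenotype network as GraphML
#'
#' Node attributes: `category` (semicolon-joined), `disease_related`,
#' `degree`, `centrality` (eigenvector centrality on the largest component,
#' NA elsewhere). Edge attributes: `jaccard`, `q_value`. The file opens
#' directly in Cytoscape.
#'
#' @param network A `phenotype_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- pn_igraph(network)
  nodes <- network$nodes
  idx <- match(igraph::V(g)$name, nodes$trait)
  cat_attr <- if (!is.null(nodes$categories)) {
    vapply(nodes$categories[idx], function(x) paste(sort(x), collapse = ";"), "")
  } else rep("", length(idx))
  dis_attr <- if (!is.null(nodes$disease_related)) {
    as.logical(nodes$disease_related[idx])
  } else rep(NA, length(idx))
  igraph::V(g)$category <- cat_attr
  igraph::V(g)$disease_related <- dis_attr
  igraph::V(g)$degree <- igraph::degree(g)
  cent <- rep(NA_real_, igraph::vcount(g))
  if (igraph::ecount(g) > 0) {
    ec <- eigenvector_centrality(network)
    cent[match(names(ec), igraph::V(g)$name)] <- unname(ec)
  }
  igraph::V(g)$centrality <- cent
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
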