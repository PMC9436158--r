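#' Build the bipartite trait-variant index
#'
#' Indexes only the retained traits. Variant sets are deduplicated; the
#' variant universe size N is the number of distinct variants across retained
#' traits (post-filtering by default, so the enrichment test is
#' self-contained under filtering).
#'
#' @param records Association records data.frame.
#' @param retained_traits Character vector of trait labels to index (e.g.
#'   `filter_traits(...)$retained$trait_label`). NULL indexes all traits.
#' @return An object of class `trait_variant_index`: list with
#'   `trait_variants`, `variant_traits`, `trait_studies` (named lists of
#'   character vectors) and `n_variants` (the universe size N).
#' @export
build_index <- function(records, retained_traits = NULL) {
  if (!is.null(retained_traits)) {
    records <- records[records$trait_label %in% retained_traits, , drop = FALSE]
  }
  traits <- sort(unique(records$trait_label))
  f <- factor(records$trait_label, levels = traits)
  trait_variants <- lapply(split(records$variant_ids, f),
                           function(x) sort(unique(unlist(x))))
  trait_studies <- lapply(split(records$pubmed_id, f),
                          function(x) sort(unique(x)))
  # invert
  all_v <- unlist(trait_variants, use.names = FALSE)
  owner <- rep(names(trait_variants), lengths(trait_variants))
  variant_traits <- lapply(split(owner, all_v), unique)
  idx <- list(trait_variants = trait_variants,
              variant_traits = variant_traits,
              trait_studies = trait_studies,
              n_variants = length(variant_traits))
  class(idx) <- "trait_variant_index"
  idx
}

#' Enumerate trait pairs sharing at least one variant
#'
#' Uses the variant -> traits inverted index; each unordered sharing pair
#' appears exactly once, with `trait_a < trait_b` lexicographically.
#'
#' @param index A `trait_variant_index`.
#' @return data.frame with columns `trait_a`, `trait_b`.
#' @export
candidate_pairs <- function(index) {
  shared <- index$variant_traits[lengths(index$variant_traits) >= 2L]
  if (!length(shared)) {
    return(data.frame(trait_a = character(0), trait_b = character(0),
                      stringsAsFactors = FALSE))
  }
  mats <- lapply(shared, function(ts) utils::combn(sort(ts), 2L))
  m <- do.call(cbind, mats)
  df <- unique(data.frame(trait_a = m[1L, ], trait_b = m[2L, ],
                          stringsAsFactors = FALSE))
  df <- df[order(df$trait_a, df$trait_b, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Jaccard index of two variant sets
#'
#' @param set_a,set_b Non-empty character vectors of variant ids.
#' @return `|A intersect B| / |A union B|`.
#' @export
jaccard <- function(set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stop("jaccard requires non-empty sets")
  a <- unique(set_a); b <- unique(set_b)
  length(intersect(a, b)) / length(union(a, b))
}

#' One-sided Fisher's exact enrichment p-value
#'
#' Given the 2x2 table of a trait pair over the variant universe (`a` shared,
#' `b` in A only, `c` in B only, `d` in neither), returns the hypergeometric
#' upper tail P(X >= a) with population N = a+b+c+d, K = a+b successes and
#' n = a+c draws — the probability of an overlap at least as large as
#' observed.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A probability.
#' @export
fisher_enrichment_p <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(counts) < 1) stop("empty universe")
  if (a == 0) return(1)
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment returning q-values in input order. Thin validated
#' wrapper over [stats::p.adjust()]; `m` defaults to `length(p_values)` and
#' can be raised to adjust within a larger test family.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Size of the test family (>= `length(p_values)`).
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop("m must be at least length(p_values)")
  stats::p.adjust(p_values, method = "BH", n = m)
}

#' Build the phenotype network
#'
#' Enumerates candidate pairs (traits sharing >= 1 variant), scores each with
#' the Jaccard index and the one-sided Fisher enrichment test over the
#' variant universe, applies Benjamini-Hochberg correction, and retains edges
#' with q <= `alpha` (the boundary is kept). By default the BH family is the
#' candidate pairs only: non-sharing pairs have p = 1 and can never become
#' significant, but `fdr_family = "all_pairs"` adjusts over all
#' choose(T, 2) pairs instead.
#'
#' @param index A `trait_variant_index`.
#' @param alpha FDR level (default 0.05).
#' @param fdr_family `"candidates"` (default) or `"all_pairs"`.
#' @param traits Optional trait table (from [map_trait_categories()]) whose
#'   `categories` / `disease_related` columns annotate the nodes.
#' @param keep_isolates Keep traits without a significant edge as isolated
#'   nodes (default FALSE; isolates are reported in provenance either way).
#' @param universe_size Override for the variant universe size N (must be at
#'   least the index's own N). Used when comparing networks built from
#'   nested record subsets, so that significance differences reflect sharing
#'   structure rather than universe shrinkage; default is the index's N.
#' @param p_threshold_override When non-NULL, retain candidate pairs with
#'   p <= this fixed cutoff instead of q <= alpha (q-values are still
#'   computed and reported). Used to hold the significance threshold of a
#'   reference network fixed when rebuilding on a record subset.
#' @return An object of class `phenotype_network`: list with `nodes`
#'   (data.frame `trait`, optionally `categories`, `disease_related`),
#'   `edges` (data.frame `trait_a`, `trait_b`, `shared_count`, `union_count`,
#'   `jaccard`, `p_value`, `q_value`, `shared_variants` list), and
#'   `provenance`.
#' @export
build_network <- function(index, alpha = 0.05,
                          fdr_family = c("candidates", "all_pairs"),
                          traits = NULL, keep_isolates = FALSE,
                          universe_size = NULL, p_threshold_override = NULL) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(index, "trait_variant_index"))
  pairs <- candidate_pairs(index)
  n_traits <- length(index$trait_variants)
  N <- if (is.null(universe_size)) index$n_variants else universe_size
  if (N < index$n_variants) {
    stop("universe_size cannot be smaller than the index's variant universe")
  }
  n_cand <- nrow(pairs)
  if (n_cand > 0) {
    tv <- index$trait_variants
    shared_variants <- vector("list", n_cand)
    a_cnt <- integer(n_cand); u_cnt <- integer(n_cand); p <- numeric(n_cand)
    for (i in seq_len(n_cand)) {
      A <- tv[[pairs$trait_a[i]]]
      B <- tv[[pairs$trait_b[i]]]
      sv <- sort(intersect(A, B))
      a <- length(sv)
      u <- length(A) + length(B) - a
      shared_variants[[i]] <- sv
      a_cnt[i] <- a
      u_cnt[i] <- u
      p[i] <- fisher_enrichment_p(a, length(A) - a, length(B) - a, N - u)
    }
    m <- if (fdr_family == "all_pairs") choose(n_traits, 2) else n_cand
    q <- bh_adjust(p, m = m)
    keep <- if (is.null(p_threshold_override)) q <= alpha
            else p <= p_threshold_override
    edges <- data.frame(trait_a = pairs$trait_a[keep],
                        trait_b = pairs$trait_b[keep],
                        shared_count = a_cnt[keep],
                        union_count = u_cnt[keep],
                        jaccard = a_cnt[keep] / u_cnt[keep],
                        p_value = p[keep],
                        q_value = q[keep],
                        stringsAsFactors = FALSE)
    edges$shared_variants <- I(shared_variants[keep])
  } else {
    m <- if (fdr_family == "all_pairs") choose(n_traits, 2) else 0L
    edges <- data.frame(trait_a = character(0), trait_b = character(0),
                        shared_count = integer(0), union_count = integer(0),
                        jaccard = numeric(0), p_value = numeric(0),
                        q_value = numeric(0), stringsAsFactors = FALSE)
    edges$shared_variants <- I(list())
  }
  edges <- edges[order(edges$trait_a, edges$trait_b, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL

  connected <- sort(unique(c(edges$trait_a, edges$trait_b)))
  all_traits <- names(index$trait_variants)
  node_names <- if (keep_isolates) all_traits else connected
  nodes <- data.frame(trait = node_names, stringsAsFactors = FALSE)
  if (!is.null(traits)) {
    i <- match(node_names, traits$trait_label)
    ok <- !is.na(i)
    cats <- vector("list", length(node_names))
    cats[] <- list("uncategorized")
    cats[ok] <- traits$categories[i[ok]]
    nodes$categories <- I(cats)
    dr <- rep(NA, length(node_names))
    dr[ok] <- traits$disease_related[i[ok]]
    nodes$disease_related <- dr
  }
  net <- list(
    nodes = nodes,
    edges = edges,
    provenance = list(alpha = alpha, n_variants = N, m = m,
                      n_candidate_pairs = n_cand, n_edges = nrow(edges),
                      n_traits_indexed = n_traits,
                      n_isolates = n_traits - length(connected),
                      fdr_family = fdr_family, keep_isolates = keep_isolates,
                      p_threshold_override = p_threshold_override)
  )
  class(net) <- "phenotype_network"
  net
}

#' Convert a phenotype network to an igraph graph
#'
#' Undirected simple graph over the network's node list with `jaccard` and
#' `q_value` edge attributes. Isolated nodes are kept if present in the node
#' table.
#'
#' @param network A `phenotype_network`.
#' @return An igraph object.
#' @export
pn_igraph <- function(network) {
  stopifnot(inherits(network, "phenotype_network"))
  el <- network$edges[, c("trait_a", "trait_b", "jaccard", "q_value")]
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = network$nodes$trait))
}

#' @export
print.phenotype_network <- function(x, ...) {
  cat("phenotype_network:", nrow(x$nodes), "traits,", nrow(x$edges),
      "edges (alpha =", x$provenance$alpha,
      ", N =", x$provenance$n_variants, "variants)\n")
  invisible(x)
}
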