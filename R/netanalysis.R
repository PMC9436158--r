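#' Degree of every network trait
#'
#' @param network A `phenotype_network`.
#' @return Named integer vector, trait -> number of incident retained edges
#'   (isolated nodes, if kept, have degree 0).
#' @export
degree_sequence <- function(network) {
  g <- pn_igraph(network)
  igraph::degree(g)
}

#' Log-binned degree distribution
#'
#' Bin n covers degrees \[2^(n-1), 2^n - 1\] (widths 1, 2, 4, 8, ...). For
#' each non-empty bin, K is the mean degree of its nodes and pK the node
#' count divided by the bin width, so that sum(pK * width) equals the number
#' of binned nodes. Degree-0 nodes are excluded with a warning (they have no
#' place on a log-log plot).
#'
#' @param degrees Integer vector of node degrees (>= 1).
#' @return data.frame with columns `lower_degree`, `width`, `n_nodes`,
#'   `mean_degree`, `p_k`; attribute `"total_nodes"` gives the binned count.
#' @export
log_binned_degree_distribution <- function(degrees) {
  if (any(degrees < 0)) stop("degrees must be non-negative")
  if (any(degrees == 0)) {
    warning("excluding ", sum(degrees == 0), " node(s) of degree 0")
    degrees <- degrees[degrees > 0]
  }
  if (!length(degrees)) {
    out <- data.frame(lower_degree = numeric(0), width = numeric(0),
                      n_nodes = integer(0), mean_degree = numeric(0),
                      p_k = numeric(0))
    attr(out, "total_nodes") <- 0L
    return(out)
  }
  bin <- floor(log2(degrees)) + 1  # bin n holds [2^(n-1), 2^n - 1]
  bins <- sort(unique(bin))
  out <- data.frame(
    lower_degree = 2^(bins - 1),
    width = 2^(bins - 1),
    n_nodes = as.integer(table(factor(bin, levels = bins))),
    mean_degree = vapply(bins, function(b) mean(degrees[bin == b]), 0)
  )
  out$p_k <- out$n_nodes / out$width
  attr(out, "total_nodes") <- length(degrees)
  out
}

#' Eigenvector centrality on the largest connected component
#'
#' Power iteration on the (by default unweighted) adjacency matrix of the
#' largest connected component, normalised to unit Euclidean norm, all
#' entries non-negative. The iteration uses the shift A + I, which has the
#' same dominant eigenvector but a strictly dominant eigenvalue even on
#' bipartite graphs (whose spectrum is symmetric, so the unshifted iteration
#' oscillates). Iteration stops when the max absolute change falls below
#' `tol`; failure to converge is an error, never a silent partial result.
#'
#' @param network A `phenotype_network` with at least one edge.
#' @param weighted Use Jaccard edge weights instead of the unweighted
#'   adjacency (default FALSE).
#' @param tol Convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 100000).
#' @return Named numeric vector of scores for the traits in the largest
#'   component.
#' @export
eigenvector_centrality <- function(network, weighted = FALSE,
                                   tol = 1e-10, max_iter = 100000L) {
  g <- pn_igraph(network)
  if (igraph::ecount(g) == 0) stop("network has no edges")
  comp <- igraph::components(g)
  lcc <- which(comp$membership == which.max(comp$csize))
  g <- igraph::induced_subgraph(g, lcc)
  A <- igraph::as_adjacency_matrix(
    g, sparse = TRUE, attr = if (weighted) "jaccard" else NULL)
  n <- nrow(A)
  x <- rep(1 / sqrt(n), n)
  for (iter in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x  # shift by +I: see above
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) stop("adjacency annihilated the iterate; no dominant eigenvector")
    y <- y / nrm
    if (max(abs(y - x)) < tol) {
      names(y) <- rownames(A)
      return(y)
    }
    x <- y
  }
  stop("eigenvector centrality did not converge within ", max_iter, " iterations")
}

#' Count retained edges each variant is responsible for
#'
#' A variant is responsible for an edge when it appears in the edge's shared
#' variant set. Output is sorted by descending edge count; a gene label per
#' variant can be joined from the association records.
#'
#' @param network A `phenotype_network`.
#' @param records Optional association records; when given, each variant is
#'   annotated with the distinct non-empty `mapped_gene` values of the rows
#'   reporting it (joined with "; ").
#' @return data.frame with columns `variant`, `n_edges`, and `gene` when
#'   `records` is supplied.
#' @export
variant_edge_counts <- function(network, records = NULL) {
  sv <- network$edges$shared_variants
  if (!length(sv)) {
    out <- data.frame(variant = character(0), n_edges = integer(0),
                      stringsAsFactors = FALSE)
    if (!is.null(records)) out$gene <- character(0)
    return(out)
  }
  tab <- sort(table(unlist(sv)), decreasing = TRUE)
  out <- data.frame(variant = names(tab), n_edges = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (!is.null(records)) {
    v <- unlist(records$variant_ids)
    gene <- rep(records$mapped_gene, lengths(records$variant_ids))
    gmap <- vapply(split(gene, v), function(gg) {
      gg <- unique(gg[nzchar(gg)])
      paste(gg, collapse = "; ")
    }, "")
    out$gene <- unname(gmap[out$variant])
    out$gene[is.na(out$gene)] <- ""
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation between degree and a node covariate
#'
#' @param network A `phenotype_network`.
#' @param covariate Named numeric vector, trait -> value (e.g. total variant
#'   count or study count). Only traits present in both the network and the
#'   covariate enter.
#' @return list with `r`, `p` (two-sided), `n`.
#' @export
degree_covariate_correlation <- function(network, covariate) {
  k <- degree_sequence(network)
  common <- intersect(names(k), names(covariate))
  if (length(common) < 3) stop("need at least 3 traits with degree and covariate")
  x <- as.numeric(k[common]); y <- as.numeric(covariate[common])
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    stop("zero-variance input; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}

#' Louvain community detection
#'
#' Multi-level greedy modularity maximisation. Community ids are relabelled
#' by descending size, contiguous from 0; isolated nodes (if kept in the
#' network) become singleton communities. Deterministic given `seed`.
#'
#' @param network A `phenotype_network`.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed RNG seed (default 0).
#' @return Object of class `community_partition`: list with `membership`
#'   (named integer vector, ids from 0), `modularity`, and `communities`
#'   (data.frame `community`, `size`, `n_disease` when node flags exist).
#' @export
detect_communities <- function(network, resolution = 1, seed = 0L) {
  g <- pn_igraph(network)
  if (igraph::vcount(g) == 0) stop("network has no nodes")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  # relabel by descending size (ties broken by smallest member name)
  sizes <- table(memb)
  first_member <- vapply(names(sizes),
                         function(id) min(names(memb)[memb == id]), "")
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  new_memb <- stats::setNames(unname(relabel[as.character(memb)]), names(memb))
  Q <- igraph::modularity(g, new_memb + 1L)
  comm_ids <- sort(unique(new_memb))
  communities <- data.frame(community = comm_ids,
                            size = as.integer(table(new_memb)[as.character(comm_ids)]))
  if (!is.null(network$nodes$disease_related)) {
    dis <- stats::setNames(network$nodes$disease_related, network$nodes$trait)
    communities$n_disease <- vapply(comm_ids, function(id) {
      sum(dis[names(new_memb)[new_memb == id]], na.rm = TRUE)
    }, 0L)
  }
  out <- list(membership = new_memb, modularity = Q, communities = communities,
              resolution = resolution, seed = seed)
  class(out) <- "community_partition"
  out
}

internal_edge_counts <- function(graph, membership, comm_ids) {
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  ca <- membership[ends[, 1]]
  cb <- membership[ends[, 2]]
  same <- ca == cb
  tab <- table(factor(ca[same], levels = comm_ids))
  as.integer(tab)
}

#' Community significance by degree-preserving rewiring
#'
#' Tests whether each community is internally denser than expected given
#' its size and the network's degree sequence. The null model is the
#' configuration model sampled by double-edge swaps (`swap_mult * |E|` swaps
#' per sample); the statistic is the community's internal edge count, and
#' p = (1 + #\{null >= observed\}) / (1 + n_null). Singleton communities
#' always get p = 1.
#'
#' @param network A `phenotype_network`.
#' @param partition A `community_partition` for this network.
#' @param n_null Number of null samples (default 1000; < 100 warns).
#' @param seed RNG seed.
#' @param swap_mult Swaps per sample, as a multiple of the edge count.
#' @return data.frame with columns `community`, `size`, `internal_edges`,
#'   `p_value`.
#' @export
community_significance <- function(network, partition, n_null = 1000L,
                                   seed = 0L, swap_mult = 10L) {
  stopifnot(inherits(partition, "community_partition"))
  if (n_null < 100) warning("n_null < 100 gives low p-value resolution")
  g <- pn_igraph(network)
  memb <- partition$membership
  if (!setequal(names(memb), igraph::V(g)$name)) {
    stop("partition does not cover the network's node set")
  }
  comm_ids <- sort(unique(memb))
  obs <- internal_edge_counts(g, memb, comm_ids)
  ge <- integer(length(comm_ids))
  set.seed(seed)
  for (i in seq_len(n_null)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = swap_mult * igraph::ecount(g)))
    ge <- ge + (internal_edge_counts(gr, memb, comm_ids) >= obs)
  }
  sizes <- as.integer(table(memb)[as.character(comm_ids)])
  data.frame(community = comm_ids, size = sizes, internal_edges = obs,
             p_value = (1 + ge) / (1 + n_null))
}

#' Traits adjacent to both members of a pair
#'
#' @param network A `phenotype_network`.
#' @param trait_a,trait_b Trait labels present in the network.
#' @return Character vector of common neighbours (excluding the pair itself).
#' @export
shared_neighbors <- function(network, trait_a, trait_b) {
  g <- pn_igraph(network)
  for (tr in c(trait_a, trait_b)) {
    if (!tr %in% igraph::V(g)$name) stop("trait not in network: ", tr)
  }
  na_ <- igraph::neighbors(g, trait_a)$name
  nb_ <- igraph::neighbors(g, trait_b)$name
  sort(setdiff(intersect(na_, nb_), c(trait_a, trait_b)))
}

#' Degree summaries per ontology category
#'
#' A trait carrying several categories contributes its degree to each of
#' them. Categories with no network trait are omitted.
#'
#' @param network A `phenotype_network` whose nodes carry `categories`.
#' @return data.frame with columns `category`, `n_traits`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
degree_by_category <- function(network) {
  if (is.null(network$nodes$categories)) stop("network nodes carry no categories")
  k <- degree_sequence(network)
  cats <- unlist(network$nodes$categories)
  deg <- rep(unname(k[network$nodes$trait]), lengths(network$nodes$categories))
  sp <- split(deg, cats)
  out <- data.frame(
    category = names(sp),
    n_traits = lengths(sp),
    t(vapply(sp, function(d) {
      q <- stats::quantile(d, c(0, .25, .5, .75, 1), names = FALSE)
      stats::setNames(q, c("min", "q1", "median", "q3", "max"))
    }, numeric(5))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-trait node summary table
#'
#' For every network trait: degree, eigenvector centrality (NA outside the
#' largest connected component), total variants, responsible variants
#' (variants shared with at least one other indexed trait), and distinct
#' studies (PubMed ids).
#'
#' @param network A `phenotype_network`.
#' @param index The `trait_variant_index` the network was built from.
#' @return data.frame sorted by descending degree.
#' @export
node_summary <- function(network, index) {
  traits <- network$nodes$trait
  k <- degree_sequence(network)[traits]
  cent <- rep(NA_real_, length(traits))
  if (nrow(network$edges) > 0) {
    ec <- eigenvector_centrality(network)
    cent[match(names(ec), traits)] <- unname(ec)
  }
  in_net <- vapply(index$variant_traits, function(ts) sum(ts %in% traits), 0L)
  shared_vs <- names(index$variant_traits)[in_net >= 2L]
  out <- data.frame(
    trait = traits,
    degree = as.integer(k),
    centrality = cent,
    total_variants = lengths(index$trait_variants[traits]),
    responsible_variants = vapply(index$trait_variants[traits], function(v) {
      sum(v %in% shared_vs)
    }, 0L),
    studies = lengths(index$trait_studies[traits]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$degree, out$trait, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
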