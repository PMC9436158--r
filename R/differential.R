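#' Split association records by study source
#'
#' Flags each record as belonging to the focal source (PubMed id in
#' `focal_pubmed_ids`) and returns the reduced record set with the focal
#' source removed, for rebuilding the no-focal network.
#'
#' @param records Association records data.frame.
#' @param focal_pubmed_ids Character vector of PubMed ids designating the
#'   focal source (e.g. the Million Veteran Program publications).
#' @return list with `flagged` (records plus logical `is_focal_source`) and
#'   `reduced` (records without the focal source).
#' @export
split_by_source <- function(records, focal_pubmed_ids) {
  if (!length(focal_pubmed_ids)) {
    warning("empty focal PubMed id list; reduced set equals the full set")
    focal_pubmed_ids <- character(0)
  }
  is_focal <- records$pubmed_id %in% focal_pubmed_ids
  if (length(focal_pubmed_ids) && !any(is_focal)) {
    warning("no record matches the focal PubMed id list")
  }
  flagged <- records
  flagged$is_focal_source <- is_focal
  list(flagged = flagged, reduced = records[!is_focal, , drop = FALSE])
}

#' Edges attributable exclusively to the focal source
#'
#' An edge is novel when it is significant in the full network but absent
#' from the network rebuilt without the focal source's records. Under
#' `mode = "compare"` (default) the reduced network should be built against
#' the full network's variant universe and significance threshold (see
#' [build_network()]'s `universe_size` and `p_threshold_override`), so the
#' comparison isolates the sharing structure the focal source contributes;
#' [run_pipeline()] arranges this. Under `mode = "intersect_only"` no
#' reduced network is needed: an edge is novel when every one of its shared
#' variants is reported exclusively by focal-source records. For each novel
#' edge the responsible focal variants are the shared variants contributed
#' only by focal-source records.
#'
#' @param full_network,reduced_network `phenotype_network`s built with the
#'   same pipeline settings (alpha, FDR family); mismatched settings error.
#'   `reduced_network` is ignored under `mode = "intersect_only"`.
#' @param flagged_records Records with `is_focal_source` (from
#'   [split_by_source()]); enables the per-edge responsible-variant report
#'   and is required for `mode = "intersect_only"`.
#' @param mode `"compare"` (default) or `"intersect_only"`.
#' @return list with `novel_edges` (edge data.frame, plus list column
#'   `focal_variants` when records are given) and `novel_nodes`.
#' @export
novel_edges <- function(full_network, reduced_network = NULL,
                        flagged_records = NULL,
                        mode = c("compare", "intersect_only")) {
  mode <- match.arg(mode)
  full_e <- full_network$edges
  if (mode == "compare") {
    if (is.null(reduced_network)) stop("mode \"compare\" needs a reduced network")
    pf <- full_network$provenance; pr <- reduced_network$provenance
    if (pf$alpha != pr$alpha || pf$fdr_family != pr$fdr_family) {
      stop("full and reduced networks were built with different pipeline settings")
    }
    red_key <- paste(reduced_network$edges$trait_a,
                     reduced_network$edges$trait_b, sep = "\r")
    full_key <- paste(full_e$trait_a, full_e$trait_b, sep = "\r")
    novel <- full_e[!(full_key %in% red_key), , drop = FALSE]
  } else {
    if (is.null(flagged_records)) {
      stop("mode \"intersect_only\" needs flagged records")
    }
    focal_only <- focal_exclusive_variants(flagged_records)
    all_focal <- vapply(full_e$shared_variants,
                        function(v) all(v %in% focal_only), TRUE)
    novel <- full_e[all_focal, , drop = FALSE]
  }
  rownames(novel) <- NULL
  if (!is.null(flagged_records)) {
    focal_only <- focal_exclusive_variants(flagged_records)
    novel$focal_variants <- I(lapply(novel$shared_variants,
                                     function(v) intersect(v, focal_only)))
  }
  list(novel_edges = novel,
       novel_nodes = sort(unique(c(novel$trait_a, novel$trait_b))))
}

focal_exclusive_variants <- function(flagged_records) {
  stopifnot("is_focal_source" %in% names(flagged_records))
  focal_v <- unique(unlist(
    flagged_records$variant_ids[flagged_records$is_focal_source]))
  nonfocal_v <- unique(unlist(
    flagged_records$variant_ids[!flagged_records$is_focal_source]))
  setdiff(focal_v, nonfocal_v)
}

#' Attach European / non-European stratum flags to records
#'
#' Joins ancestry annotations by study accession and sets `has_european`
#' when any rolled label is in `european_labels` and `has_non_european` when
#' any rolled label is outside it. The flags are not mutually exclusive:
#' multi-ancestry studies carry both. Records without an annotation get both
#' flags FALSE (and are thereby excluded from stratified builds).
#'
#' @param records Association records data.frame.
#' @param annotations Ancestry table from [parse_ancestry_table()].
#' @param european_labels Broad labels counted as European (default
#'   `"European"`).
#' @return `records` with logical columns `has_european`, `has_non_european`.
#' @export
stratum_flags <- function(records, annotations,
                          european_labels = "European") {
  i <- match(records$study_accession, annotations$study_accession)
  has_eur <- rep(FALSE, nrow(records))
  has_non <- rep(FALSE, nrow(records))
  ok <- !is.na(i)
  if (any(!ok)) {
    message(sum(!ok), " record(s) lack ancestry annotation and are excluded from strata")
  }
  labs <- annotations$rolled_labels[i[ok]]
  has_eur[ok] <- vapply(labs, function(l) any(l %in% european_labels), TRUE)
  has_non[ok] <- vapply(labs, function(l) any(!(l %in% european_labels)), TRUE)
  records$has_european <- has_eur
  records$has_non_european <- has_non
  records
}

#' Build the European and non-European networks
#'
#' Replicates the full assembly pipeline on each stratum's record subset
#' (the FDR is recomputed within each subset). Under the default
#' `european_mode = "any"` a record enters the European network when its
#' study includes any European population and the non-European network when
#' it includes any non-European population; dual-ancestry records enter
#' both. `european_mode = "only"` restricts the European network to
#' European-only studies and puts every other annotated record in the
#' non-European network.
#'
#' @param flagged_records Records with stratum flags (from [stratum_flags()]).
#' @param retained_traits Optional trait labels to restrict to.
#' @param alpha,fdr_family,traits,keep_isolates Passed to [build_network()].
#' @param european_mode `"any"` (default) or `"only"`.
#' @return list with `european` and `non_european` networks.
#' @export
build_stratified_networks <- function(flagged_records, retained_traits = NULL,
                                      alpha = 0.05,
                                      fdr_family = "candidates",
                                      traits = NULL, keep_isolates = FALSE,
                                      european_mode = c("any", "only")) {
  european_mode <- match.arg(european_mode)
  stopifnot(all(c("has_european", "has_non_european") %in% names(flagged_records)))
  annotated <- flagged_records$has_european | flagged_records$has_non_european
  if (european_mode == "any") {
    eur <- flagged_records$has_european
    non <- flagged_records$has_non_european
  } else {
    eur <- flagged_records$has_european & !flagged_records$has_non_european
    non <- annotated & !eur
  }
  build_one <- function(sub) {
    if (!nrow(sub)) {
      warning("empty stratum; returning an empty network")
    }
    build_network(build_index(sub, retained_traits), alpha = alpha,
                  fdr_family = fdr_family, traits = traits,
                  keep_isolates = keep_isolates)
  }
  list(european = build_one(flagged_records[eur, , drop = FALSE]),
       non_european = build_one(flagged_records[non, , drop = FALSE]))
}

#' Binary neighborhood vectors over the shared trait set
#'
#' For each trait present in both networks, builds a pair of 0/1 vectors
#' indexed by the other shared traits (fixed lexicographic order, the focal
#' trait excluded): entry 1 when the trait is adjacent to that index trait
#' in the corresponding network.
#'
#' @param net_a,net_b `phenotype_network`s.
#' @return Named list, trait -> list(a = vector, b = vector, index = trait
#'   names); empty (with a warning) when the networks share no traits.
#' @export
neighborhood_vectors <- function(net_a, net_b) {
  shared <- sort(intersect(net_a$nodes$trait, net_b$nodes$trait))
  if (!length(shared)) {
    warning("networks share no traits")
    return(list())
  }
  adj <- function(net) {
    e <- net$edges
    nb <- c(split(e$trait_b, factor(e$trait_a, levels = shared)),
            split(e$trait_a, factor(e$trait_b, levels = shared)))
    lapply(split(unlist(nb, use.names = FALSE),
                 rep(names(nb), lengths(nb))), unique)
  }
  adj_a <- adj(net_a); adj_b <- adj(net_b)
  out <- lapply(shared, function(tr) {
    idx <- setdiff(shared, tr)
    list(a = as.integer(idx %in% adj_a[[tr]]),
         b = as.integer(idx %in% adj_b[[tr]]),
         index = idx)
  })
  names(out) <- shared
  out
}

#' Per-trait neighborhood-vector correlations and histogram
#'
#' Pearson correlation between each shared trait's two neighborhood vectors;
#' traits with a zero-variance vector on either side are reported with
#' `r = NA` (undefined) and excluded from the histogram and the
#' below-threshold fraction.
#'
#' @param vector_pairs Output of [neighborhood_vectors()].
#' @param breaks Histogram bin edges (default width 0.1 over \[-1, 1\]).
#' @param threshold Report the fraction of defined correlations strictly
#'   below this value (default 0.4).
#' @return list with `correlations` (data.frame `trait`, `r`, `n`),
#'   `histogram` (data.frame `lower`, `upper`, `count`), and
#'   `frac_below_threshold`.
#' @export
neighborhood_correlation <- function(vector_pairs,
                                     breaks = seq(-1, 1, by = 0.1),
                                     threshold = 0.4) {
  traits <- names(vector_pairs)
  r <- vapply(vector_pairs, function(vp) {
    stopifnot(length(vp$a) == length(vp$b))
    if (length(vp$a) < 2 || stats::sd(vp$a) == 0 || stats::sd(vp$b) == 0) {
      return(NA_real_)
    }
    stats::cor(vp$a, vp$b)
  }, 0)
  n <- vapply(vector_pairs, function(vp) length(vp$a), 0L)
  defined <- r[!is.na(r)]
  h <- if (length(defined)) {
    hist_counts <- graphics::hist(defined, breaks = breaks, plot = FALSE,
                                  right = FALSE, include.lowest = TRUE)$counts
    data.frame(lower = utils::head(breaks, -1), upper = breaks[-1],
               count = hist_counts)
  } else {
    data.frame(lower = utils::head(breaks, -1), upper = breaks[-1],
               count = 0L)
  }
  list(
    correlations = data.frame(trait = traits, r = unname(r), n = unname(n),
                              stringsAsFactors = FALSE),
    histogram = h,
    frac_below_threshold = if (length(defined)) mean(defined < threshold) else NA_real_
  )
}
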