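#' Configuration for the synthetic catalog generator
#'
#' The generator plants clusters of traits drawing variants from shared
#' per-cluster pools (so within-cluster pairs overlap strongly), sprinkles
#' cross-cluster noise and private variants, adds background variants that
#' mostly touch a single trait, and plants focal-source-exclusive trait
#' pairs whose shared variants are reported only under `focal_pubmed_id`.
#' Study ancestry labels follow a European-only / non-European-only / dual
#' mixture and are not mutually exclusive.
#'
#' @param n_clusters Number of planted trait clusters.
#' @param traits_per_cluster Traits per cluster.
#' @param cluster_pool_size Variants in each cluster's shared pool.
#' @param within_share_prob Probability a trait carries a given pool variant.
#' @param cross_noise_prob Probability a trait picks up a given foreign-pool
#'   variant.
#' @param private_variants_per_trait Variants unique to each trait.
#' @param background_variants Extra universe variants attached to one trait
#'   each (a second trait with probability 0.1).
#' @param n_focal_pairs Planted focal-exclusive trait pairs.
#' @param focal_variants_per_pair Shared variants per focal pair.
#' @param focal_pubmed_id PubMed id under which all focal records appear.
#' @param studies_per_trait Studies (accession + PubMed id) per cluster trait.
#' @param ancestry_fractions Named numeric mixture over
#'   `european`, `non_european`, `dual`; must sum to 1.
#' @param n_decoy_traits Number of decoy traits (labels that the keyword /
#'   explicit filters must remove) drawing variants from the cluster pools.
#' @param seed Integer seed; fully determines the output.
#' @return Validated config list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_clusters = 4L, traits_per_cluster = 12L,
                             cluster_pool_size = 30L,
                             within_share_prob = 0.5,
                             cross_noise_prob = 0.02,
                             private_variants_per_trait = 2L,
                             background_variants = 100L,
                             n_focal_pairs = 15L,
                             focal_variants_per_pair = 4L,
                             focal_pubmed_id = "99000001",
                             studies_per_trait = 3L,
                             ancestry_fractions = c(european = 0.5,
                                                    non_european = 0.3,
                                                    dual = 0.2),
                             n_decoy_traits = 2L,
                             seed = 42L) {
  cfg <- as.list(environment())
  probs <- c(within_share_prob, cross_noise_prob, ancestry_fractions)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(ancestry_fractions) - 1) > 1e-9) {
    stop("ancestry_fractions must sum to 1")
  }
  counts <- c(n_clusters, traits_per_cluster, cluster_pool_size,
              private_variants_per_trait, background_variants, n_focal_pairs,
              focal_variants_per_pair, studies_per_trait, n_decoy_traits)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_clusters > 0 && traits_per_cluster < 1) {
    stop("traits_per_cluster must be >= 1 when clusters are requested")
  }
  if (n_decoy_traits > 2) stop("at most 2 decoy traits are defined")
  class(cfg) <- "synthetic_config"
  cfg
}

stage_seed <- function(seed, offset) (as.integer(seed) %% 1000000L) * 1000L + offset

#' Generate a synthetic GWAS-Catalog-style dataset with ground truth
#'
#' @param config A [synthetic_config()].
#' @return list with:
#'   \describe{
#'     \item{associations}{data.frame using GWAS-Catalog headers
#'       (`STUDY ACCESSION`, `PUBMEDID`, `MAPPED_TRAIT`, `MAPPED_TRAIT_URI`,
#'       `SNPS`, `MAPPED_GENE`, `P-VALUE`); some cells pack several variants
#'       or EFO URIs to exercise the parser.}
#'     \item{ancestry}{data.frame `STUDY ACCESSION`,
#'       `BROAD ANCESTRAL CATEGORY` (one row per study-label).}
#'     \item{category_map}{data.frame `uri`, `category`.}
#'     \item{truth}{list: `clusters` (trait -> planted label; focal pairs
#'       get their own labels), `focal_pairs` (data.frame `trait_a`,
#'       `trait_b`, `variants` list), `focal_pubmed_id`, `study_ancestry`.}
#'   }
#' @export
generate_catalog <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  v_counter <- 0L
  new_variants <- function(n) {
    out <- sprintf("rs%07d", v_counter + seq_len(n))
    v_counter <<- v_counter + n
    out
  }

  ## --- stage 1: trait variant sets -------------------------------------
  set.seed(stage_seed(cfg$seed, 1L))
  pools <- replicate(cfg$n_clusters, new_variants(cfg$cluster_pool_size),
                     simplify = FALSE)
  trait_sets <- list()
  truth_clusters <- character(0)
  for (c_i in seq_len(cfg$n_clusters)) {
    for (t_i in seq_len(cfg$traits_per_cluster)) {
      label <- sprintf("synthetic disease c%d-%02d", c_i, t_i)
      own <- pools[[c_i]][stats::runif(cfg$cluster_pool_size) < cfg$within_share_prob]
      cross <- unlist(lapply(setdiff(seq_len(cfg$n_clusters), c_i), function(j) {
        pools[[j]][stats::runif(cfg$cluster_pool_size) < cfg$cross_noise_prob]
      }))
      priv <- new_variants(cfg$private_variants_per_trait)
      trait_sets[[label]] <- unique(c(own, cross, priv))
      truth_clusters[label] <- sprintf("C%d", c_i)
    }
  }
  cluster_traits <- names(trait_sets)
  # background variants: one host trait each, a second with prob 0.1
  if (cfg$background_variants > 0 && length(cluster_traits)) {
    bg <- new_variants(cfg$background_variants)
    for (v in bg) {
      hosts <- sample(cluster_traits, 1L)
      if (stats::runif(1) < 0.1 && length(cluster_traits) > 1) {
        hosts <- c(hosts, sample(setdiff(cluster_traits, hosts), 1L))
      }
      for (h in hosts) trait_sets[[h]] <- c(trait_sets[[h]], v)
    }
  }
  # decoy traits that the trait filter must remove
  decoy_labels <- c("synthetic protein measurement", "age at onset")
  decoys <- utils::head(decoy_labels, cfg$n_decoy_traits)
  for (d in decoys) {
    src <- unlist(pools)
    trait_sets[[d]] <- if (length(src)) sample(src, min(3L, length(src))) else new_variants(3L)
    truth_clusters[d] <- "decoy"
  }

  ## --- stage 2: focal-exclusive pairs ----------------------------------
  set.seed(stage_seed(cfg$seed, 2L))
  focal_pairs <- data.frame(trait_a = character(0), trait_b = character(0),
                            stringsAsFactors = FALSE)
  focal_pairs$variants <- I(list())
  focal_traits <- character(0)
  if (cfg$n_focal_pairs > 0) {
    fa <- sprintf("synthetic focal disease f%02da", seq_len(cfg$n_focal_pairs))
    fb <- sprintf("synthetic focal disease f%02db", seq_len(cfg$n_focal_pairs))
    vlist <- vector("list", cfg$n_focal_pairs)
    for (i in seq_len(cfg$n_focal_pairs)) {
      shared <- new_variants(cfg$focal_variants_per_pair)
      vlist[[i]] <- shared
      trait_sets[[fa[i]]] <- c(shared, new_variants(cfg$private_variants_per_trait))
      trait_sets[[fb[i]]] <- c(shared, new_variants(cfg$private_variants_per_trait))
      truth_clusters[fa[i]] <- sprintf("F%d", i)
      truth_clusters[fb[i]] <- sprintf("F%d", i)
    }
    focal_pairs <- data.frame(trait_a = pmin(fa, fb), trait_b = pmax(fa, fb),
                              stringsAsFactors = FALSE)
    focal_pairs$variants <- I(vlist)
    focal_traits <- c(fa, fb)
  }

  ## --- stage 3: traits -> URIs, categories, genes ----------------------
  all_traits <- names(trait_sets)
  uri_of <- stats::setNames(
    sprintf("http://purl.obolibrary.org/obo/SYN_%06d", seq_along(all_traits)),
    all_traits)
  disease_cats <- c("cardiovascular disease", "immune system disorder",
                    "cancer", "nervous system disorder", "metabolic disease",
                    "digestive system disorder")
  cat_rows <- data.frame(uri = unname(uri_of), stringsAsFactors = FALSE)
  cat_rows$category <- ifelse(
    all_traits %in% decoys, "other measurement",
    disease_cats[(seq_along(all_traits) - 1L) %% length(disease_cats) + 1L])
  # every 5th cluster trait gets a second URI in a measurement category
  second_uri <- stats::setNames(rep(NA_character_, length(all_traits)), all_traits)
  multi <- cluster_traits[seq_along(cluster_traits) %% 5L == 0L]
  if (length(multi)) {
    extra <- sprintf("http://purl.obolibrary.org/obo/SYNB_%06d", seq_along(multi))
    second_uri[multi] <- extra
    cat_rows <- rbind(cat_rows, data.frame(uri = extra,
                                           category = "hematological measurement",
                                           stringsAsFactors = FALSE))
  }
  all_variants <- sort(unique(unlist(trait_sets)))
  gene_of <- stats::setNames(
    sprintf("SYNGENE%04d", seq_along(all_variants)), all_variants)

  ## --- stage 4: studies and association rows ---------------------------
  set.seed(stage_seed(cfg$seed, 3L))
  study_counter <- 0L
  pubmed_counter <- 0L
  rows <- list()
  emit_rows <- function(trait, variants, accession, pubmed) {
    uris <- uri_of[[trait]]
    if (!is.na(second_uri[[trait]])) uris <- c(uris, second_uri[[trait]])
    uri_cell <- paste(uris, collapse = ", ")
    i <- 1L
    while (i <= length(variants)) {
      take <- 1L
      sep <- NULL
      if (i < length(variants)) {
        u <- stats::runif(1)
        if (u < 0.08) { take <- 2L; sep <- "; " }
        else if (u < 0.11) { take <- 2L; sep <- " x " }
      }
      vs <- variants[i:(i + take - 1L)]
      rows[[length(rows) + 1L]] <<- data.frame(
        `STUDY ACCESSION` = accession, PUBMEDID = pubmed,
        MAPPED_TRAIT = trait, MAPPED_TRAIT_URI = uri_cell,
        SNPS = paste(vs, collapse = if (is.null(sep)) "" else sep),
        MAPPED_GENE = paste(unname(gene_of[vs]), collapse = ", "),
        `P-VALUE` = format(10^stats::runif(1, -12, -5), digits = 6),
        check.names = FALSE, stringsAsFactors = FALSE)
      i <- i + take
    }
  }
  study_ancestry <- list()
  nonfocal_traits <- setdiff(all_traits, focal_traits)
  for (trait in nonfocal_traits) {
    n_st <- max(1L, cfg$studies_per_trait)
    accs <- sprintf("GCST%06d", study_counter + seq_len(n_st))
    pmids <- sprintf("3%07d", pubmed_counter + seq_len(n_st))
    study_counter <- study_counter + n_st
    pubmed_counter <- pubmed_counter + n_st
    assign_st <- sample(n_st, length(trait_sets[[trait]]), replace = TRUE)
    for (s in seq_len(n_st)) {
      vs <- trait_sets[[trait]][assign_st == s]
      if (length(vs)) emit_rows(trait, vs, accs[s], pmids[s])
      study_ancestry[[accs[s]]] <- NA  # filled in stage 5
    }
  }
  for (trait in focal_traits) {
    acc <- sprintf("GCST9%05d", study_counter + 1L)
    study_counter <- study_counter + 1L
    emit_rows(trait, trait_sets[[trait]], acc, cfg$focal_pubmed_id)
    study_ancestry[[acc]] <- NA
  }
  associations <- do.call(rbind, rows)
  rownames(associations) <- NULL

  ## --- stage 5: ancestry labels per study ------------------------------
  set.seed(stage_seed(cfg$seed, 4L))
  non_eur_raw <- c("Sub-Saharan African", "East Asian",
                   "Hispanic or Latin American", "African unspecified",
                   "South Asian")
  accs <- names(study_ancestry)
  scheme <- sample(c("european", "non_european", "dual"), length(accs),
                   replace = TRUE, prob = cfg$ancestry_fractions[
                     c("european", "non_european", "dual")])
  anc_rows <- lapply(seq_along(accs), function(i) {
    labs <- switch(scheme[i],
                   european = "European",
                   non_european = sample(non_eur_raw, 1L),
                   dual = c("European", sample(non_eur_raw, 1L)))
    data.frame(`STUDY ACCESSION` = accs[i], `BROAD ANCESTRAL CATEGORY` = labs,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  ancestry <- do.call(rbind, anc_rows)
  rownames(ancestry) <- NULL

  list(associations = associations,
       ancestry = ancestry,
       category_map = cat_rows,
       truth = list(clusters = truth_clusters,
                    focal_pairs = focal_pairs,
                    focal_pubmed_id = cfg$focal_pubmed_id,
                    study_ancestry = stats::setNames(scheme, accs)),
       config = cfg)
}

#' Write a synthetic catalog to disk
#'
#' Writes `associations.tsv`, `ancestry.tsv`, `category_map.tsv` and
#' `truth.json` under `dir`.
#'
#' @param catalog Output of [generate_catalog()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(catalog$associations, file.path(dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(catalog$ancestry, file.path(dir, "ancestry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(catalog$category_map, file.path(dir, "category_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- catalog$truth
  # as.list keeps trait names; write_json drops names of atomic vectors
  truth$clusters <- as.list(truth$clusters)
  truth$focal_pairs <- list(trait_a = truth$focal_pairs$trait_a,
                            trait_b = truth$focal_pairs$trait_b,
                            variants = truth$focal_pairs$variants)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Score pipeline output against planted ground truth
#'
#' @param truth Ground truth from [generate_catalog()].
#' @param partition Optional `community_partition`; scored by Adjusted Rand
#'   Index against the planted cluster labels of the partitioned traits.
#' @param differential Optional result of [novel_edges()]; scored by exact
#'   precision/recall of the recovered edge set against the planted
#'   focal-exclusive pairs.
#' @return list with any of `ari`, `precision`, `recall`.
#' @export
evaluate_recovery <- function(truth, partition = NULL, differential = NULL) {
  out <- list()
  if (!is.null(partition)) {
    traits <- names(partition$membership)
    planted <- truth$clusters[traits]
    if (any(is.na(planted))) {
      stop("partition contains traits absent from the planted truth")
    }
    out$ari <- mclust::adjustedRandIndex(planted, partition$membership)
  }
  if (!is.null(differential)) {
    rec <- differential$novel_edges
    rec_key <- paste(pmin(rec$trait_a, rec$trait_b),
                     pmax(rec$trait_a, rec$trait_b), sep = "\r")
    pl <- truth$focal_pairs
    pl_key <- paste(pmin(pl$trait_a, pl$trait_b),
                    pmax(pl$trait_a, pl$trait_b), sep = "\r")
    tp <- length(intersect(rec_key, pl_key))
    out$precision <- if (length(rec_key)) tp / length(rec_key) else
      (if (length(pl_key)) 0 else 1)
    out$recall <- if (length(pl_key)) tp / length(pl_key) else 1
  }
  out
}
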