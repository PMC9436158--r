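test_that("split_by_source partitions records and warns on degenerate input", {
  recs <- records_from_sets(stats::setNames(as.list(sprintf("v%d", 1:10)),
                                            sprintf("T%02d", 1:10)),
                            pubmed = c(rep("focal", 3), sprintf("pm%d", 1:7)))
  out <- split_by_source(recs, "focal")
  expect_equal(nrow(out$reduced), 7L)
  expect_equal(sum(out$flagged$is_focal_source), 3L)
  expect_warning(all_kept <- split_by_source(recs, "absent"), "no record")
  expect_equal(nrow(all_kept$reduced), 10L)
  expect_warning(split_by_source(recs, character(0)), "empty")
  everything <- split_by_source(recs, unique(recs$pubmed_id))
  expect_equal(nrow(everything$reduced), 0L)
})

test_that("focal-only variants create novel edges with responsible variants", {
  # A and B share nothing without the focal study, which adds v5 to both
  base <- records_from_sets(list(A = c("a1", "a2"), B = c("b1", "b2"),
                                 C = c("c1", "c2")))
  focal <- records_from_sets(list(A = "v5", B = "v5"), pubmed = "MVP")
  recs <- rbind(base, focal)
  src <- split_by_source(recs, "MVP")
  full <- build_network(build_index(recs), alpha = 1)
  reduced <- build_network(build_index(src$reduced), alpha = 1,
                           universe_size = full$provenance$n_variants)
  nov <- novel_edges(full, reduced, src$flagged)
  expect_equal(nrow(nov$novel_edges), 1L)
  expect_equal(nov$novel_nodes, c("A", "B"))
  expect_equal(nov$novel_edges$focal_variants[[1]], "v5")
})

test_that("duplicated focal associations create no novel edges", {
  base <- records_from_sets(list(A = c("v1", "v2"), B = c("v1", "v2"),
                                 C = "c1"))
  focal <- records_from_sets(list(A = "v1", B = "v2"), pubmed = "MVP")
  recs <- rbind(base, focal)
  src <- split_by_source(recs, "MVP")
  full <- build_network(build_index(recs), alpha = 1)
  reduced <- build_network(build_index(src$reduced), alpha = 1,
                           universe_size = full$provenance$n_variants)
  nov <- novel_edges(full, reduced, src$flagged)
  expect_equal(nrow(nov$novel_edges), 0L)
  # intersect-only mode agrees here
  nov2 <- novel_edges(full, flagged_records = src$flagged,
                      mode = "intersect_only")
  expect_equal(nrow(nov2$novel_edges), 0L)
})

test_that("mismatched pipeline settings are rejected", {
  net1 <- network_from_sets(list(A = "v1", B = "v1"), alpha = 0.05)
  net2 <- network_from_sets(list(A = "v1", B = "v1"), alpha = 0.1)
  expect_error(novel_edges(net1, net2), "different pipeline settings")
})

test_that("stratum flags follow the roll-up and are not mutually exclusive", {
  recs <- records_from_sets(list(A = "v1", B = "v2", C = "v3", D = "v4"))
  ann <- data.frame(study_accession = recs$study_accession[1:3],
                    stringsAsFactors = FALSE)
  ann$raw_labels <- I(list("European", "Sub-Saharan African",
                           c("European", "East Asian")))
  ann$rolled_labels <- I(list("European", "African",
                              c("European", "East Asian")))
  expect_message(out <- stratum_flags(recs, ann), "lack ancestry")
  expect_equal(out$has_european, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$has_non_european, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("stratified builds replicate the pipeline per record subset", {
  sets <- list(A = c("v1", "v2"), B = c("v1", "v2"), C = c("v3", "v4"),
               D = c("v3", "v4"))
  recs <- records_from_sets(sets)
  recs$has_european <- c(TRUE, TRUE, TRUE, TRUE)
  recs$has_non_european <- c(FALSE, FALSE, TRUE, TRUE)
  nets <- build_stratified_networks(recs, alpha = 1)
  key <- function(net) paste(net$edges$trait_a, net$edges$trait_b)
  expect_setequal(key(nets$european), c("A B", "C D"))
  expect_setequal(key(nets$non_european), "C D")
  # dual-ancestry records feed both networks
  expect_true("C" %in% nets$european$nodes$trait &&
                "C" %in% nets$non_european$nodes$trait)
  # identical subsets give identical networks
  recs$has_non_european <- rep(TRUE, 4)
  nets2 <- build_stratified_networks(recs, alpha = 1)
  expect_identical(nets2$european$edges, nets2$non_european$edges)
  # european_mode = "only" removes dual studies from the European side
  recs$has_non_european <- c(FALSE, FALSE, TRUE, TRUE)
  recs$has_european <- c(TRUE, TRUE, TRUE, FALSE)
  nets3 <- build_stratified_networks(recs, alpha = 1, european_mode = "only")
  expect_setequal(key(nets3$european), "A B")
  expect_setequal(key(nets3$non_european), "C D")
})

test_that("stratified builds are invariant to record order", {
  prep <- prepared_catalog(synthetic_config(seed = 13))
  ann <- parse_ancestry_table(file.path(prep$dir, "ancestry.tsv"))
  flagged <- stratum_flags(prep$records, ann)
  nets_a <- build_stratified_networks(flagged,
                                      prep$filtered$retained$trait_label)
  set.seed(1)
  perm <- flagged[sample(nrow(flagged)), , drop = FALSE]
  nets_b <- build_stratified_networks(perm,
                                      prep$filtered$retained$trait_label)
  for (side in c("european", "non_european")) {
    ea <- nets_a[[side]]$edges; eb <- nets_b[[side]]$edges
    rownames(ea) <- rownames(eb) <- NULL
    expect_equal(ea, eb)
  }
})

test_that("neighborhood vectors index shared traits minus the focal trait", {
  net_a <- pn_from_edges(list(c("x", "a"), c("x", "b"), c("c", "d")),
                         nodes = c("x", "a", "b", "c", "d"))
  net_b <- pn_from_edges(list(c("x", "a"), c("x", "b"), c("c", "d")),
                         nodes = c("x", "a", "b", "c", "d"))
  vp <- neighborhood_vectors(net_a, net_b)
  expect_setequal(names(vp), c("x", "a", "b", "c", "d"))
  expect_equal(vp$x$index, c("a", "b", "c", "d"))
  expect_equal(vp$x$a, vp$x$b)
  expect_equal(vp$x$a, c(1, 1, 0, 0))
  # identical networks: identical vectors for every trait
  for (tr in names(vp)) expect_equal(vp[[tr]]$a, vp[[tr]]$b)
  expect_warning(neighborhood_vectors(net_a, pn_from_edges(list(c("q", "r")))),
                 "share no traits")
})

test_that("a trait isolated on one side gets an all-zero vector", {
  net_a <- pn_from_edges(list(c("x", "a"), c("a", "b")),
                         nodes = c("x", "a", "b"))
  net_b <- pn_from_edges(list(c("a", "b")), nodes = c("x", "a", "b"))
  vp <- neighborhood_vectors(net_a, net_b)
  expect_equal(vp$x$b, c(0, 0))
  expect_equal(vp$x$a, c(1, 0))
})

test_that("neighborhood correlations handle identity, inversion and zero variance", {
  vp <- list(
    same = list(a = c(1, 0, 1), b = c(1, 0, 1), index = c("p", "q", "r")),
    anti = list(a = c(1, 0, 0), b = c(0, 1, 1), index = c("p", "q", "r")),
    flat = list(a = c(0, 0, 0), b = c(1, 0, 1), index = c("p", "q", "r")))
  out <- neighborhood_correlation(vp)
  r <- stats::setNames(out$correlations$r, out$correlations$trait)
  expect_equal(unname(r[["same"]]), 1)
  expect_equal(unname(r[["anti"]]), -1)
  expect_true(is.na(r[["flat"]]))
  expect_equal(sum(out$histogram$count), 2L)  # NA excluded
  expect_equal(out$frac_below_threshold, 0.5)
})
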