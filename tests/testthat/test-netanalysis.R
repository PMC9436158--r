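test_that("degree sequence counts incident retained edges", {
  tri <- pn_from_edges(list(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(sort(unname(degree_sequence(tri))), c(2, 2, 2))
  star <- pn_from_edges(list(c("hub", "l1"), c("hub", "l2"), c("hub", "l3")))
  k <- degree_sequence(star)
  expect_equal(unname(k[["hub"]]), 3)
  expect_equal(sum(k), 2 * 3)
  empty <- pn_from_edges(list())
  expect_length(degree_sequence(empty), 0)
})

test_that("log binning reproduces the hand-binned example for degrees 1-8", {
  dd <- log_binned_degree_distribution(1:8)
  expect_equal(dd$lower_degree, c(1, 2, 4, 8))
  expect_equal(dd$width, c(1, 2, 4, 8))
  expect_equal(dd$mean_degree, c(1, 2.5, 5.5, 8))
  expect_equal(dd$p_k, c(1, 1, 1, 0.125))
})

test_that("log binning conserves node counts on arbitrary inputs", {
  set.seed(3)
  for (i in 1:25) {
    degs <- sample(1:500, sample(1:60, 1), replace = TRUE)
    dd <- log_binned_degree_distribution(degs)
    expect_equal(sum(dd$p_k * dd$width), length(degs))
    expect_equal(sum(dd$n_nodes), length(degs))
    expect_true(all(dd$width == 2^(log2(dd$lower_degree))))
  }
  dd1 <- log_binned_degree_distribution(rep(1, 7))
  expect_equal(nrow(dd1), 1L)
  expect_equal(dd1$p_k, 7)
  expect_warning(log_binned_degree_distribution(c(0, 1, 2)), "degree 0")
})

test_that("eigenvector centrality matches closed forms", {
  tri <- pn_from_edges(list(c("a", "b"), c("b", "c"), c("a", "c")))
  ec <- eigenvector_centrality(tri)
  expect_equal(unname(ec), rep(1 / sqrt(3), 3), tolerance = 1e-8)
  star <- pn_from_edges(list(c("hub", "l1"), c("hub", "l2"), c("hub", "l3")))
  ec2 <- eigenvector_centrality(star)
  expect_equal(unname(ec2[["hub"]]), 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(unname(ec2[["l1"]]), 1 / sqrt(6), tolerance = 1e-8)
  expect_equal(sqrt(sum(ec2^2)), 1, tolerance = 1e-10)
})

test_that("centrality is restricted to the largest connected component", {
  two <- pn_from_edges(list(c("a", "b"), c("b", "c"), c("x", "y")))
  ec <- eigenvector_centrality(two)
  expect_setequal(names(ec), c("a", "b", "c"))
  expect_error(eigenvector_centrality(pn_from_edges(list())), "no edges")
})

test_that("centrality matches the dense eigendecomposition oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    g <- igraph::sample_gnp(n, min(1, 2.5 / n + 0.05))
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership == which.max(comp$csize)))
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- sprintf("n%02d", seq_len(igraph::vcount(g)))
    el <- igraph::as_edgelist(g)
    net <- pn_from_edges(lapply(seq_len(nrow(el)), function(r) el[r, ]))
    ec <- eigenvector_centrality(net)
    ref <- oracle_eigencentrality(pn_igraph(net))
    expect_equal(ec[sort(names(ec))], ref[sort(names(ref))], tolerance = 1e-8)
  }
})

test_that("variant edge counts attribute retained edges to shared variants", {
  sets <- list(A = c("v1", "a1"), B = c("v1", "b1"), C = c("v1", "c1"),
               D = c("d1", "d2"))
  net <- network_from_sets(sets, alpha = 1)
  vec <- variant_edge_counts(net)
  expect_equal(vec$variant[1], "v1")
  expect_equal(vec$n_edges[1], 3L)
  expect_false("d1" %in% vec$variant)
  expect_gte(sum(vec$n_edges), nrow(net$edges))
  recs <- records_from_sets(sets)
  recs$mapped_gene <- c("G1", "G1", "G2", "")
  vec2 <- variant_edge_counts(net, recs)
  expect_equal(vec2$gene[vec2$variant == "v1"], "G1; G2")
})

test_that("variants on FDR-failed pairs contribute no edge counts", {
  # two traits share v9 only weakly: significant at alpha=1, not at 1e-6
  sets <- list(A = c("v9", "a1", "a2"), B = c("v9", "b1", "b2"))
  net <- network_from_sets(sets, alpha = 1e-6)
  expect_equal(nrow(variant_edge_counts(net)), 0L)
})

test_that("degree-covariate correlation matches the direct formula", {
  net <- pn_from_edges(list(c("a", "b"), c("b", "c"), c("c", "d"), c("b", "d")))
  k <- degree_sequence(net)
  lin <- 2 * k + 1
  expect_equal(degree_covariate_correlation(net, lin)$r, 1, tolerance = 1e-12)
  inv <- stats::setNames(max(k) + 1 - as.numeric(k), names(k))
  expect_equal(degree_covariate_correlation(net, inv)$r, -1, tolerance = 1e-12)
  cov <- stats::setNames(c(1, 1, 2, 5), names(k))
  direct <- stats::cor(as.numeric(k[names(cov)]), as.numeric(cov))
  expect_equal(degree_covariate_correlation(net, cov)$r, direct,
               tolerance = 1e-12)
  expect_error(degree_covariate_correlation(net, stats::setNames(rep(1, 4),
                                                                 names(k))),
               "zero-variance")
})

test_that("Louvain separates two cliques joined by one edge", {
  cl1 <- sprintf("a%d", 1:5); cl2 <- sprintf("b%d", 1:5)
  edges <- c(utils::combn(cl1, 2, simplify = FALSE),
             utils::combn(cl2, 2, simplify = FALSE),
             list(c("a1", "b1")))
  net <- pn_from_edges(edges)
  part <- detect_communities(net, seed = 0)
  expect_equal(nrow(part$communities), 2L)
  expect_length(unique(part$membership[cl1]), 1)
  expect_length(unique(part$membership[cl2]), 1)
  expect_false(part$membership[["a1"]] == part$membership[["b2"]])
  expect_setequal(part$communities$community, 0:1)
  expect_gt(part$modularity, 0.3)
})

test_that("single cliques collapse to one community, isolates to singletons", {
  clique <- pn_from_edges(utils::combn(sprintf("x%d", 1:6), 2, simplify = FALSE))
  expect_equal(nrow(detect_communities(clique, seed = 0)$communities), 1L)
  iso <- pn_from_edges(list(), nodes = c("i1", "i2", "i3"))
  part <- detect_communities(iso, seed = 0)
  expect_equal(sort(unname(part$membership)), 0:2)
})

test_that("community detection is deterministic given the seed", {
  net <- prepared_network_cache$net
  p1 <- detect_communities(net, seed = 5)
  p2 <- detect_communities(net, seed = 5)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$modularity, p2$modularity)
})

test_that("rewiring significance flags planted cliques but not random splits", {
  set.seed(8)
  # planted 6-clique on top of a sparse random background
  bg <- igraph::sample_gnp(30, 0.05)
  igraph::V(bg)$name <- sprintf("n%02d", 1:30)
  clique_nodes <- sprintf("n%02d", 1:6)
  edges <- unique(c(
    lapply(seq_len(igraph::ecount(bg)), function(i) {
      igraph::as_edgelist(bg)[i, ]
    }),
    utils::combn(clique_nodes, 2, simplify = FALSE)))
  edges <- edges[!vapply(edges, function(e) e[1] == e[2], TRUE)]
  net <- pn_from_edges(edges, nodes = sprintf("n%02d", 1:30))
  memb <- stats::setNames(as.integer(!(net$nodes$trait %in% clique_nodes)),
                          net$nodes$trait)
  part <- structure(list(membership = memb, modularity = 0,
                         communities = data.frame(community = 0:1,
                                                  size = c(6L, 24L))),
                    class = "community_partition")
  sig <- community_significance(net, part, n_null = 200, seed = 1)
  expect_lte(sig$p_value[sig$community == 0], 0.05)
})

test_that("singleton communities always get p = 1", {
  net <- pn_from_edges(list(c("a", "b"), c("c", "d")),
                       nodes = c("a", "b", "c", "d", "lone"))
  part <- detect_communities(net, seed = 0)
  sig <- suppressWarnings(community_significance(net, part, n_null = 50, seed = 0))
  expect_equal(sig$p_value[sig$size == 1], 1)
})

test_that("arbitrary halves of an Erdos-Renyi graph are rarely significant", {
  hits <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    set.seed(s)
    g <- igraph::sample_gnp(24, 0.25)
    igraph::V(g)$name <- sprintf("n%02d", 1:24)
    el <- igraph::as_edgelist(g)
    net <- pn_from_edges(lapply(seq_len(nrow(el)), function(r) el[r, ]),
                         nodes = igraph::V(g)$name)
    memb <- stats::setNames(rep(0:1, each = 12), net$nodes$trait)
    part <- structure(list(membership = memb, modularity = 0,
                           communities = data.frame(community = 0:1,
                                                    size = c(12L, 12L))),
                      class = "community_partition")
    sig <- community_significance(net, part, n_null = 100, seed = s)
    if (any(sig$p_value <= 0.05)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)  # not significant in >= 90% of seeds
})

test_that("shared neighbors follow adjacency set intersection", {
  tri <- pn_from_edges(list(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(shared_neighbors(tri, "a", "b"), "c")
  two_stars <- pn_from_edges(list(c("h1", "x"), c("h2", "y")))
  expect_length(shared_neighbors(two_stars, "h1", "h2"), 0)
  k5 <- pn_from_edges(utils::combn(sprintf("k%d", 1:5), 2, simplify = FALSE))
  expect_length(shared_neighbors(k5, "k1", "k2"), 3)
  expect_error(shared_neighbors(tri, "a", "zzz"), "not in network")
})

test_that("degree-by-category summaries duplicate multi-category traits", {
  sets <- list(A = c("v1", "v2"), B = c("v1", "v2"), C = c("v2", "v3"))
  recs <- records_from_sets(sets)
  cmap <- data.frame(uri = sprintf("uri:%s", c("A", "B", "C", "C")),
                     category = c("cancer", "cancer", "cancer",
                                  "metabolic disease"))
  traits <- map_trait_categories(recs, cmap)
  net <- build_network(build_index(recs), alpha = 1, traits = traits)
  dbc <- degree_by_category(net)
  expect_true(all(c("cancer", "metabolic disease") %in% dbc$category))
  kC <- unname(degree_sequence(net)[["C"]])
  expect_equal(dbc$median[dbc$category == "metabolic disease"], kC)
  expect_equal(dbc$n_traits[dbc$category == "cancer"], 3L)
})

test_that("node summaries report degree, sharing and study counts", {
  sets <- list(A = c("v1", "v2", "a1"), B = c("v1", "v2"), C = c("v2", "c1"))
  recs <- records_from_sets(sets)
  idx <- build_index(recs)
  net <- build_network(idx, alpha = 1)
  summ <- node_summary(net, idx)
  rowA <- summ[summ$trait == "A", ]
  expect_equal(rowA$total_variants, 3L)
  expect_equal(rowA$responsible_variants, 2L)  # v1, v2 shared; a1 private
  expect_equal(rowA$studies, 1L)
  expect_true(all(summ$responsible_variants <= summ$total_variants))
  expect_equal(summ$degree, sort(summ$degree, decreasing = TRUE))
})
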