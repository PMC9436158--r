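# Independent brute-force references used to cross-check the implementation.
# These deliberately avoid the code paths under test: the Fisher tail is an
# explicit binomial-coefficient enumeration, BH is the step-up formula
# written out, pair enumeration is all-pairs intersection, and eigenvector
# centrality comes from a dense eigendecomposition.

oracle_fisher <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + b
  n <- a + c
  if (a == 0) return(1)
  ks <- a:min(K, n)
  sum(vapply(ks, function(k) choose(K, k) * choose(N - K, n - k), 0)) /
    choose(N, n)
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- pmin(rev(cummin(rev(q_sorted))), 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# All-pairs reference network from named variant sets.
oracle_network <- function(sets, alpha = 0.05) {
  traits <- sort(names(sets))
  N <- length(unique(unlist(sets)))
  rows <- list()
  if (length(traits) >= 2) {
    for (i in seq_len(length(traits) - 1)) {
      for (j in (i + 1):length(traits)) {
        A <- unique(sets[[traits[i]]]); B <- unique(sets[[traits[j]]])
        shared <- sort(intersect(A, B))
        if (!length(shared)) next
        a <- length(shared)
        u <- length(union(A, B))
        rows[[length(rows) + 1L]] <- list(
          trait_a = traits[i], trait_b = traits[j], shared_count = a,
          union_count = u, jaccard = a / u,
          p_value = oracle_fisher(a, length(A) - a, length(B) - a, N - u),
          shared_variants = shared)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(trait_a = character(0), trait_b = character(0),
                      shared_count = integer(0), union_count = integer(0),
                      jaccard = numeric(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  df <- data.frame(
    trait_a = vapply(rows, `[[`, "", "trait_a"),
    trait_b = vapply(rows, `[[`, "", "trait_b"),
    shared_count = vapply(rows, `[[`, 0L, "shared_count"),
    union_count = vapply(rows, `[[`, 0L, "union_count"),
    jaccard = vapply(rows, `[[`, 0, "jaccard"),
    p_value = vapply(rows, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE)
  df$shared_variants <- I(lapply(rows, `[[`, "shared_variants"))
  df$q_value <- oracle_bh(df$p_value)
  df[df$q_value <= alpha, , drop = FALSE]
}

oracle_eigencentrality <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  dec <- eigen(A, symmetric = TRUE)
  v <- dec$vectors[, 1]
  if (sum(v) < 0) v <- -v
  stats::setNames(v / sqrt(sum(v^2)), rownames(A))
}

# Random small trait/variant instances for the oracle-equivalence property.
random_variant_sets <- function(seed) {
  set.seed(seed)
  n_traits <- sample(2:12, 1)
  n_vars <- sample(3:30, 1)
  vars <- sprintf("rs%03d", seq_len(n_vars))
  sets <- lapply(seq_len(n_traits), function(i) {
    sample(vars, sample.int(min(8L, n_vars), 1))
  })
  names(sets) <- sprintf("T%02d", seq_len(n_traits))
  sets
}
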