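#!/usr/bin/env Rscript
# Degree structure of the network: log-binned degree distribution,
# eigenvector centrality, degree vs study/variant covariates, and
# per-variant edge participation.

source("analysis/00_prepare.R")

deg <- degree_sequence(network)
dd <- log_binned_degree_distribution(deg[deg > 0])
utils::write.table(dd, "results/degree_distribution.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cent <- eigenvector_centrality(network)
top <- utils::head(sort(cent, decreasing = TRUE), 10)
cat("top eigenvector-centrality traits:\n")
print(round(top, 4))

n_variants <- lengths(index$trait_variants)
n_studies <- lengths(index$trait_studies)
cv <- degree_covariate_correlation(network, n_variants)
cs <- degree_covariate_correlation(network, n_studies)
cat(sprintf("degree ~ variants: r = %.3f (p = %.2e, n = %d)\n",
            cv$r, cv$p, cv$n))
cat(sprintf("degree ~ studies:  r = %.3f (p = %.2e, n = %d)\n",
            cs$r, cs$p, cs$n))

vec <- variant_edge_counts(network, parsed$records)
utils::write.table(utils::head(vec, 50), "results/variant_edge_counts.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

summ <- node_summary(network, index)
utils::write.table(summ[, setdiff(names(summ), "responsible_variants")],
                   "results/node_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/degree_distribution.tsv, results/variant_edge_counts.tsv,",
    "results/node_summary.tsv\n")
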