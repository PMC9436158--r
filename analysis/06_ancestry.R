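#!/usr/bin/env Rscript
# Ancestry-stratified networks (European vs non-European study strata) and
# per-trait neighborhood-vector correlations between them.

source("analysis/00_prepare.R")

annotations <- parse_ancestry_table("data/synthetic/ancestry.tsv")
flagged <- stratum_flags(parsed$records, annotations)
strata <- build_stratified_networks(flagged, filtered$retained$trait_label,
                                    traits = filtered$retained)
write_edge_table(strata$european$edges, "results/edges_european.tsv")
write_edge_table(strata$non_european$edges, "results/edges_non_european.tsv")
cat("European edges:    ", nrow(strata$european$edges), "\n")
cat("non-European edges:", nrow(strata$non_european$edges), "\n")

nc <- neighborhood_correlation(neighborhood_vectors(strata$european,
                                                    strata$non_european))
utils::write.table(nc$correlations, "results/neighborhood_correlations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(nc$histogram, "results/correlation_histogram.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("traits with r < 0.4: %.1f%% of %d with defined r\n",
            100 * nc$frac_below_threshold, sum(!is.na(nc$correlations$r))))
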