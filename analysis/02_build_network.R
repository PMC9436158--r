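#!/usr/bin/env Rscript
# Build the trait-trait network (Jaccard weights, one-sided Fisher
# enrichment, Benjamini-Hochberg FDR) and write the edge table and GraphML.

source("analysis/00_prepare.R")

cat("records parsed:    ", nrow(parsed$records), "\n")
cat("records dropped:   ", sum(parsed$dropped), "\n")
cat("traits retained:   ", nrow(filtered$retained),
    " (removed ", nrow(filtered$removed), ")\n", sep = "")
print(network)

write_edge_table(network$edges, "results/edges.tsv")
write_network_graphml(network, "results/network.graphml")
cat("wrote results/edges.tsv and results/network.graphml\n")
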