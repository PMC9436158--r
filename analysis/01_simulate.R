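#!/usr/bin/env Rscript
# Generate the synthetic association catalog used by the downstream
# analysis scripts and write it to data/synthetic/.

library(phenonet)

config <- synthetic_config(seed = 1)
catalog <- generate_catalog(config)
write_catalog(catalog, "data/synthetic")

cat("traits:        ", length(catalog$truth$clusters), "\n")
cat("planted pairs: ", nrow(catalog$truth$focal_pairs), "\n")
cat("catalog rows:  ", nrow(catalog$associations), "\n")
cat("studies:       ", length(unique(catalog$associations[["STUDY ACCESSION"]])), "\n")
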