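# Shared preparation sourced by scripts 02-06: parse the catalog written
# by 01_simulate.R, map categories, filter traits and build the index.

library(phenonet)

if (!file.exists("data/synthetic/associations.tsv")) {
  stop("run analysis/01_simulate.R first")
}

parsed <- parse_association_table("data/synthetic/associations.tsv")
category_map <- utils::read.delim("data/synthetic/category_map.tsv",
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE)
truth <- jsonlite::read_json("data/synthetic/truth.json",
                             simplifyVector = TRUE)
truth$clusters <- unlist(truth$clusters)

traits <- map_trait_categories(parsed$records, category_map)
filtered <- filter_traits(traits)
index <- build_index(parsed$records, filtered$retained$trait_label)
network <- build_network(index, traits = filtered$retained)

dir.create("results", showWarnings = FALSE)
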