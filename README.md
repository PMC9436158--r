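# phenonet

Phenotype networks from GWAS association catalogs: traits become nodes,
and two traits are linked when they share more associated genetic
variants than expected by chance. The package builds these networks from
GWAS-Catalog-style association tables, finds and tests their community
structure, extracts the differential subnetwork contributed by a single
focal data source, compares networks across ancestry strata, and ships a
synthetic-catalog generator with planted ground truth for end-to-end
validation.

## The model

Let each trait \(t\) have a variant set \(V_t\), the union of the SNPs
reported for it at genome-wide significance (default
\(p \le 10^{-5}\) after parsing; configurable). For a pair of traits
\((i, j)\) over a universe of \(N\) distinct variants:

- **Edge weight** — Jaccard similarity
  \(J_{ij} = |V_i \cap V_j| / |V_i \cup V_j|\).
- **Edge significance** — one-sided Fisher's exact test on the 2×2 table
  \((a, b; c, d)\) with \(a = |V_i \cap V_j|\),
  \(b = |V_i \setminus V_j|\), \(c = |V_j \setminus V_i|\),
  \(d = N - a - b - c\), testing enrichment of the overlap. This is the
  hypergeometric upper tail
  \(p = P(X \ge a)\), computed as
  `phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)`.
- **Multiple testing** — Benjamini–Hochberg across the family of tested
  pairs (by default the candidate pairs that share at least one variant;
  optionally all \(\binom{n}{2}\) pairs). Edges with \(q \le 0.05\) are
  retained.

On top of that network:

- **Communities** — Louvain modularity maximisation
  (`igraph::cluster_louvain`), with per-community significance against a
  degree-preserving rewiring null (`igraph::rewire(keeping_degseq())`),
  \(p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n_{\text{null}})\).
- **Differential subnetwork** — remove all records from a focal source
  (PubMed id set), rebuild, and report *novel edges*: significant in the
  full network, absent in the reduced one. The reduced build keeps the
  full network's variant universe and realized p-value cutoff so that
  only the loss of shared variants — not shifts in the test background
  or the FDR family — can make an edge novel.
- **Ancestry comparison** — split studies into European / non-European
  strata, build one network per stratum, and correlate each trait's
  binary neighborhood vectors (Pearson) between the two networks.

## Worked example

Four traits over a five-variant universe: `T1 = {v1,v2,v3}`,
`T2 = {v2,v3,v4}` (two shared variants), and `T3 = T4 = {v9}`.

```r
library(phenonet)
records <- data.frame(
  study_accession = c("GCST001", "GCST002", "GCST003", "GCST004"),
  pubmed_id = c("111", "222", "333", "444"),
  trait_label = c("T1", "T2", "T3", "T4"),
  mapped_gene = "",
  p_value = 1e-8)
records$efo_uris <- I(as.list(paste0("uri:", records$trait_label)))
records$variant_ids <- I(list(c("v1", "v2", "v3"), c("v2", "v3", "v4"),
                              "v9", "v9"))
index <- build_index(records)
fisher_enrichment_p(2, 1, 1, 1)   # T1-T2: 2 shared of N = 5
#> [1] 0.7
fisher_enrichment_p(1, 0, 0, 4)   # T3-T4: 1 shared of N = 5
#> [1] 0.2
```

Sharing two of five variants is unremarkable (p = 0.7), while the
perfect single-variant overlap of the two singleton traits gives
p = 0.2. After BH adjustment (q = 0.7 and 0.4) nothing survives
α = 0.05; at α = 0.5 one edge remains:

```r
net <- build_network(index, alpha = 0.5)
net
#> phenotype_network: 2 traits, 1 edges (alpha = 0.5 , N = 5 variants)
net$edges[, c("trait_a", "trait_b", "jaccard", "p_value", "q_value")]
#>   trait_a trait_b jaccard p_value q_value
#> 1      T3      T4       1     0.2     0.4
```

## The analysis workflow

`analysis/01_simulate.R` through `analysis/06_ancestry.R` run the whole
study on a generated catalog (four planted 12-trait clusters, 15
focal-exclusive trait pairs, decoy traits removed by the keyword
filter), writing tables under `results/`. With the default
configuration at seed 1 the run gives:

- 78 retained traits, 273 edges (q ≤ 0.05), N = 436 variants;
- Louvain modularity Q = 0.776; the four planted clusters are recovered
  exactly (Adjusted Rand Index 1.000) and each is significant against
  1000 degree-preserving rewires (p ≈ 0.001);
- all 15 planted focal-exclusive pairs recovered as novel edges with
  precision = recall = 1;
- 183 European-stratum vs 88 non-European-stratum edges, with 28.9% of
  the traits present in both strata showing neighborhood-vector
  correlation below 0.4;
- node degree correlates strongly with a trait's total variant count
  (r = 0.955) and study count (r = 0.996).

The same end-to-end run is available as a single call:
`run_pipeline(pipeline_config(...))` (or a YAML file with the same
fields), which writes edge tables, GraphML, community and differential
tables, ancestry comparisons and a `provenance.json`.

## Package layout

- `R/catalog_io.R` — catalog parsing (multi-SNP fields, ancestry
  annotations), edge-table and GraphML round-trip I/O.
- `R/trait_filter.R` — EFO-category mapping and the non-disease
  keyword/exclusion filter.
- `R/netbuild.R` — trait–variant index, candidate pairs, Jaccard,
  Fisher enrichment, BH, network assembly.
- `R/netanalysis.R` — degrees, log-binned degree distributions,
  eigenvector centrality, Louvain communities and rewiring significance,
  per-variant edge participation.
- `R/differential.R` — focal-source split, novel edges,
  ancestry-stratified networks and neighborhood correlations.
- `R/synthetic.R` — catalog generator with planted truth and recovery
  scoring.
- `R/pipeline.R` — configuration plus the one-call pipeline.

See `vignettes/phenotype-networks.Rmd` for methods details and the
reasoning behind the defaults.
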