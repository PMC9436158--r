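---
title: "Phenotype networks from shared GWAS variants: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype networks from shared GWAS variants: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenonet)
```

## Model and assumptions

A GWAS association catalog reports, per study row, one or more mapped
traits and one or more SNPs. `phenonet` collapses this to one variant
set per trait label, $V_t$, keeping only associations at or below a
reported-p-value threshold (default $10^{-5}$). The modelling
assumptions are:

- **Trait identity is the mapped label.** Rows with the same
  `MAPPED_TRAIT` string are the same trait, regardless of study; their
  variant sets are unioned and duplicates collapse.
- **Variants are exchangeable tokens.** Linkage disequilibrium,
  effect sizes and allele frequencies are ignored; two traits are
  related exactly insofar as they cite the same rs-ids.
- **The universe is what the catalog saw.** The Fisher background
  $N$ is the number of distinct variants across the retained traits,
  not the genome.

Non-disease traits are removed before network construction: any label
matching the word `measurement` or starting with `response to`, plus an
explicit exclusion list (`age at onset`, `age at diagnosis`). Mapped
EFO categories annotate nodes but do not themselves filter.

## Edge statistics

For traits $i, j$ with $a = |V_i \cap V_j|$, $b = |V_i| - a$,
$c = |V_j| - a$, $d = N - a - b - c$:

- weight $J_{ij} = a / (a + b + c)$;
- one-sided Fisher enrichment p-value, the hypergeometric upper tail
  $P(X \ge a)$ with $X \sim \mathrm{Hypergeom}(N, a+b, a+c)$, computed
  via `phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)` — exact,
  vectorisable, and immune to the factorial overflow of naive
  enumeration;
- Benjamini–Hochberg adjustment via `stats::p.adjust(method = "BH")`
  over the tested family, retaining $q \le \alpha$ (default 0.05).

Two FDR families are offered. The default, `"candidates"`, adjusts only
over pairs sharing at least one variant — pairs with $a = 0$ have
$p = 1$ and can never form an edge, so excluding them from the family
is the less conservative and computationally natural choice (the
candidate pairs are enumerated from the inverted variant→traits index
rather than all $\binom{n}{2}$ combinations). `"all_pairs"` adjusts
over $\binom{n}{2}$, which can only shrink the edge set.

One property worth stating because it is easy to assume and false:
with $N$, $|V_i|$, $|V_j|$ all fixed, $p$ *is* non-increasing in $a$,
but adding a *new shared variant* to both sets (increasing $a$ and both
set sizes with $N$ fixed) can increase $p$ — e.g. $N = 5$,
$|V_i| = 1, |V_j| = 4, a = 1$ gives $p = 0.8$, while growing both sets
by one shared variant forces the overlap and gives $p = 1$. The test
suite checks the true monotonicity, not the false one.

## Network analysis

- **Degree distributions** are log-binned: bin $n$ covers degrees
  $[2^{n-1}, 2^n - 1]$ and reports count divided by bin width, so the
  binned mass conserves the node count.
- **Eigenvector centrality** uses power iteration on $A + I$. The
  shift is load-bearing: bipartite-like components have symmetric
  spectra $\pm\lambda$ and unshifted iteration oscillates forever. The
  iteration runs on the largest connected component, normalises to unit
  $L_2$ norm, stops at $\|x_{k+1} - x_k\|_\infty < 10^{-10}$, and
  errors rather than returning an unconverged vector.
- **Communities** come from `igraph::cluster_louvain` under a fixed
  RNG seed; ids are relabelled 0, 1, … by descending size so output is
  stable. Significance of each community's internal edge count is
  assessed against `n_null` degree-preserving rewirings
  (`igraph::rewire(keeping_degseq(niter = 10 * |E|))`) with the
  add-one estimator $p = (1 + \#\{\text{null} \ge \text{obs}\}) /
  (1 + n_{\text{null}})$, which never reports $p = 0$.

## Differential (focal-source) subnetworks

Removing one source's records and rebuilding naively changes two
nuisance quantities along with the signal:

1. **The universe shrinks.** Variants reported only by the focal
   source leave $N$, raising everyone else's $d$-cell deficit and
   flipping borderline background edges. `build_network()` therefore
   accepts `universe_size` so the reduced network is tested against the
   full network's $N$.
2. **The FDR family shifts.** The focal source contributes
   ultra-significant pairs whose tiny p-values lower other pairs'
   BH ranks; removing them can push a borderline pair's $q$ across
   $\alpha$ with its $p$ unchanged. The pipeline's default
   (`novel_mode = "common_threshold"`) sidesteps this by retaining, in
   the reduced network, every pair with $p$ at or below the full
   network's realized BH cutoff (`max(full$edges$p_value)`), via
   `p_threshold_override`.

A *novel edge* is then one significant in the full network and absent
in the reduced one, and with both corrections it is exactly an edge
whose shared variants are focal-exclusive. `novel_mode = "recompute"`
(independent BH on the reduced network) and `"intersect_only"` (no
reduced network; novel = every edge whose shared variants are all
focal-flagged) remain available.

## Ancestry comparison

Studies are labelled European / non-European / both from the broad
ancestral category of their accession (after a rollup map of catalog
category strings). One network is built per stratum (`european_mode =
"any"` counts dual-ancestry studies in both; `"only"` makes European
exclusive). For each trait in both networks, its neighborhoods are
encoded as binary indicator vectors over the shared non-focal trait
set, and compared by Pearson correlation; traits with a zero-variance
vector get `NA`. Results are summarised as a histogram on
$[-1, 1]$ in steps of 0.1 and the fraction below 0.4.

## The synthetic generator

`synthetic_config()` defaults plant a structure the pipeline should
recover:

| parameter | default | role |
|---|---|---|
| `n_clusters` × `traits_per_cluster` | 4 × 12 | planted communities |
| `pool_variants_per_cluster` | 30 | within-cluster shared pool |
| `within_share_prob` / `cross_share_prob` | 0.5 / 0.02 | pool sampling |
| `private_variants_per_trait` | 2 | node-degree noise |
| `background_variants` | 100 | universe padding |
| `n_focal_pairs` | 15 | focal-exclusive trait pairs |
| `focal_variants_per_pair` | 4 | shared variants per focal pair |
| `studies_per_trait` | 3 | duplicate-reporting structure |
| ancestry fractions | 0.5 / 0.3 / 0.2 | European / non-Eur. / dual |

`focal_variants_per_pair` deserves a note: a pair sharing a *single*
variant that appears nowhere else yields, in a realistic universe
($N \approx 400$), a Fisher p-value far above any sane $\alpha$, so a
one-variant plant is unrecoverable by construction. Four shared
exclusive variants put the planted pairs comfortably past the BH
cutoff without making them trivial. Two decoy traits (a synthetic
"measurement" label and `age at onset`) verify the filter runs; each
fifth cluster trait gets a second EFO mapping to exercise multi-URI
handling, and generated SNP fields occasionally use `;`/`x` multi-SNP
syntax to exercise the parser.

All stage randomness derives from the single config seed through fixed
offsets (`(seed %% 1e6) * 1000 + offset`), keeping every derived seed
below $2^{31}$ and every stage reproducible in isolation.

The generator emulates catalog *format and combinatorics*, not
genetics: no LD structure, no per-variant effect sizes, no realistic
degree heavy tails. It validates bookkeeping and inference mechanics,
not biological realism.

## Numerical and I/O choices

- Floating-point columns in edge tables are serialised as `%.17g`, so
  write → read round-trips are byte-identical and bit-exact.
- Edge tables are sorted with `method = "radix"` (locale-independent)
  on the canonical pair `(trait_a < trait_b)`.
- `provenance.json` records config, input MD5 checksums and counts —
  no timestamps, so repeated runs diff clean.

## Problem sizes and limitations

The default synthetic study has ~80 traits, ~1100 catalog rows,
~440 variants and ~270 edges; the full pipeline including 1000
rewiring nulls runs in well under a minute. The quadratic candidate
enumeration and dense brute-force oracles in the tests are sized for
hundreds of traits; applying the package to a full real catalog
(tens of thousands of trait labels) would keep the inverted-index
construction cheap but make `"all_pairs"` FDR and the rewiring null
the slow steps. Other limitations: trait identity by label ignores
EFO synonymy; the Fisher background treats variants as independent
(LD inflates apparent sharing); and the ancestry rollup is only as
good as the catalog's broad ancestral categories.
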