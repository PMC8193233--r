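# clppnet

Community-level physiological profiles and co-occurrence networks for
pore-water microbiomes.

## The problem

Peatlands store a large share of terrestrial carbon, and the bacterial
communities in their pore water respond to two entangled drivers: the water
table (WT) and temperature (pore-water temperature, PWT). Disentangling them
requires looking at two layers at once — who is there (16S rRNA OTU tables)
and what they do with carbon (Biolog EcoMicroplate sole-carbon-source
profiles). `clppnet` implements that paired analysis as a tested, seeded R
pipeline for anyone with an OTU table, sample metadata with environmental
covariates, and plate absorbance series.

## What it computes

**CLPP metrics (EcoPlate).** With `Ci` the mean differential absorbance
(A590 − A750) of a substrate's replicate wells and `R` the water-control
mean, negative `Ci − R` is clamped to 0 and, over the n = 31 substrates:

- AWCD = Σ(Ci − R)/n — overall carbon-utilisation rate,
- McIntosh U = √Σ(Ci − R)² — the Euclidean-norm diversity of the response,
- Shannon H′ = −Σ Pi ln Pi with Pi = (Ci − R)/Σ(Ci − R),
- Rsi = (Ci − R)/AWCD — inoculum-density-normalised responses, analysed by
  column-centred PCA and six-guild (carbohydrates, amino acids, amines,
  esters, carboxylic acids, alcohols) mean profiles.

**Diversity.** Single-draw rarefaction, observed OTUs, Chao1
(S + F1²/2F2, bias-corrected when F2 = 0), Shannon, Faith's PD; Bray–Curtis /
binary Jaccard / Euclidean distances; PCoA; one-way PERMANOVA with the
(count+1)/(n\_perm+1) estimator; OLS diversity–covariate regressions.

**RDA.** Y centred, X standardised, Ŷ = X(XᵀX)⁻¹XᵀY; constrained variance
fractions from the SVD of Ŷ; Monte-Carlo permutation tests overall and per
predictor.

**Co-occurrence network.** OTUs above 0.1% mean relative abundance plus the
environmental variables; Spearman screen with t-approximation p-values and
one BH-FDR family; edges where |ρ| > 0.7 and q < 0.01; node
(degree, betweenness, closeness, eigenvector) and graph (density, clustering,
path length, diameter, greedy modularity) topology; 1,000 G(n, m)
Erdős–Rényi null replicates with z-scores; degree power-law check; top-k
betweenness keystones.

**Indicator species.** IndVal (group-mean specificity × fidelity,
√(A·B)), 999 label permutations, BH-FDR over OTUs, selection at
indval > 0.85 and q < 0.05.

**Synthetic data.** `scenario_config()` + `generate_scenario()` emulate the
study design the analysis assumes: 3 seasonal groups × 12 samples,
environmental covariates drawn from per-month mean ± SD profiles, 600 OTUs
with planted correlation modules and planted indicator OTUs, a random
coalescent phylogeny, and logistic EcoPlate kinetics (≈24 h lag, rapid
24–72 h rise, plateau past ≈168 h, temperature-scaled rates). Ground-truth
accessors (`score_module_recovery()`, `score_indicator_recovery()`) make
end-to-end recovery measurable.

## Worked example

```r
library(clppnet)

cfg <- scenario_config(seed = 7)          # default study conditions
meta <- gen_metadata(cfg)
gen  <- gen_otu_table(cfg, meta)
plates <- gen_plate_series(cfg, meta[1:2, ])

clpp_metrics(plates, time_h = 72)
#> # A tibble: 2 × 6
#>   sample_id time_h n_substrates  awcd mcintosh_u shannon_h
#>   <chr>      <dbl>        <int> <dbl>      <dbl>     <dbl>
#> 1 May_01        72           31  1.11       6.47      3.39
#> 2 May_02        72           31  1.07       6.12      3.41
```

AWCD ≈ 1.1 says the May communities reduce the tetrazolium dye briskly by
72 h; U ≈ 6 and H′ ≈ 3.4 (close to the ln 31 ≈ 3.43 ceiling) say that the
response is spread across nearly all 31 substrates.

```r
abundant <- filter_abundant(rarefy(gen$table, 39000, seed = 1))
env <- as.matrix(meta[, c("DOC","DO","ORP","EC","pH","PWT","WT")])
rownames(env) <- meta$sample_id

g  <- build_network(correlation_screen(relative_abundance(abundant), env))
gt <- graph_topology(g)
glance(gt)[, c("n_nodes", "n_edges", "modularity")]
#> # A tibble: 1 × 3
#>   n_nodes n_edges modularity
#>     <dbl>   <dbl>      <dbl>
#> 1      49     134      0.806

score_module_recovery(gen$truth, gt$module_of)
#> # A tibble: 1 × 3
#>     ari n_scored n_planted
#>   <dbl>    <int>     <int>
#> 1     1       32        32
```

The greedy partition recovers the four planted correlation modules exactly
(adjusted Rand index 1 over the 32 planted OTUs).

The whole analysis runs as one call (or from the shell via
`inst/scripts/clppnet.R generate|validate|run`):

```r
generate_scenario(cfg, "bundle")
run_pipeline(pipeline_config(
  otu_table = "bundle/otu_table.tsv", metadata = "bundle/metadata.tsv",
  plates = "bundle/plates", tree = "bundle/tree.nwk",
  outdir = "out", seed = 7))
```

writing per-stage TSVs, a GraphML network, `report.json` and a hashed
`MANIFEST.tsv`; a rerun with the same config and seed is byte-identical.

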