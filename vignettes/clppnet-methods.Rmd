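---
title: "Methods behind clppnet: CLPP metrics, co-occurrence networks and indicator species for pore-water microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind clppnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clppnet)
```

`clppnet` analyses paired observations of a peatland pore-water microbiome:
an OTU count table from 16S rRNA amplicon sequencing and Biolog
EcoMicroplate absorbance series describing the community's sole-carbon-source
utilisation. This vignette explains the models and procedures, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## Community-level physiological profiling

A standard EcoPlate carries 31 carbon substrates plus a water control, each
in triplicate. For a snapshot time `t` (default 72 h — the window after the
lag phase where colour development discriminates best), the per-substrate
response is

- `Ci`: the mean over the substrate's replicate wells of the differential
  absorbance A590 − A750 (the 750 nm read removes turbidity),
- `R`: the same quantity for the water-control wells,
- working value: `max(Ci − R, 0)`.

Negative blank-corrected values carry no information about dye reduction,
so they are clamped to zero **before every downstream metric** — AWCD,
McIntosh U, Shannon H′, Rsi, guild means and the PCA all see the clamped
vector. Replicate wells are averaged per substrate before clamping; a
single-replicate layout can be supplied as a TSV if a plate was read
differently.

The metrics, for `n = 31` substrates:

| metric | formula | units / range | meaning |
|---|---|---|---|
| AWCD | Σ(Ci−R)/n | OD units, ≥ 0 | overall utilisation rate |
| McIntosh U | sqrt(Σ(Ci−R)²) | OD units, ≥ 0 | norm-based diversity |
| Shannon H′ | −Σ Pi ln Pi | [0, ln n] | evenness of utilisation |
| Rsi | (Ci−R)/AWCD | sums to n | density-normalised response |

Two renderings of the McIntosh index circulate (with and without the square
root); the square-root form is implemented because only it is dimensionally
an OD quantity and consistent with values near 5–6 when AWCD is near 1 on a
31-well plate (U = AWCD·√31 for a perfectly even response).

Wells with zero clamped response are excluded from the Shannon sum
(`0·ln 0 := 0`); a plate whose every response is zero is reported as
degenerate rather than given an arbitrary H′.

Guild profiles average the clamped responses within each of the six
substrate guilds (carbohydrates, amino acids, amines, esters, carboxylic
acids, alcohols). The **mean** rather than the sum is used so that guilds
with different substrate counts (10 carbohydrates vs 1 alcohol) are
comparable. The guild assignment of the 31 standard substrates ships as
`eco_layout()`.

The CLPP ordination is a column-centred, unscaled PCA of the Rsi matrix.
Normalising by AWCD already removes the dominant inoculum-density effect,
and further unit-variance scaling would inflate substrates with nearly
constant response, so it is deliberately not applied.

## Diversity analysis

Rarefaction is a **single** uniform subsample without replacement per sample
at a common depth (default 40,205 reads, auto-lowered to the smallest sample
total with a warning). A single draw, not an average over draws, keeps the
table integer-valued for downstream presence/absence work; the seed is
recorded in the output attributes.

Chao1 is `S + F1²/(2·F2)`; with no doubletons the bias-corrected form
`S + F1(F1−1)/(2(F2+1))` avoids the division by zero. Faith's PD is the
rooted variant (branch path to the root included) via `picante`; for trees
that are unrooted in `ape`'s sense (basal polytomy) the spanning-subtree
form is the natural limit and is used. Jaccard distances are computed on
presence/absence, the usual companion to Bray–Curtis in microbiome work.

PCoA reports **all** eigenvalues, including negative ones arising from
non-Euclidean distances; explained fractions are taken over the positive
part and no Lingoes/Cailliez correction is applied, so the user sees the
raw geometry.

PERMANOVA is the one-way design: pseudo-F from the among/within
decomposition of squared distances, free permutation of sample labels, and
the add-one estimator `p = (#{F* ≥ F} + 1)/(n_perm + 1)`, which can never
report p = 0. `vegan::adonis2` is used in the test suite as an independent
cross-check of F and R².

## RDA

Redundancy analysis centres the response matrix, standardises the predictors
(the covariates arrive in mg/L, mV, °C, cm — unit variance makes their
scores comparable), and takes the least-squares fit
`Ŷ = X(XᵀX)⁻¹XᵀY`. The SVD of `Ŷ` yields the constrained axes; the
constrained fraction is `‖Ŷ‖²/‖Yc‖²`. Significance is a simple Monte-Carlo
test: rows of `X` are permuted freely against the constrained-trace
statistic (no residual permutation, matching the plain Monte-Carlo scheme of
classic ordination software); per-predictor p-values permute only that
predictor's column. Collinear predictors are rejected with the offending
columns named rather than silently dropped.

## Co-occurrence network

Only OTUs whose **mean** relative abundance across samples exceeds 0.1%
enter the screen. "Abundance above a threshold across all samples" can also
be read as "in every sample" or "in any sample"; the mean is the common
convention and both alternatives remain available via the `rule` argument.

The screen computes Spearman's rho for every unordered pair of columns —
OTU–OTU, OTU–environment and environment–environment — as the Pearson
correlation of mid-ranks, with the t-approximation p-value on n−2 degrees of
freedom. At network scale (10⁴–10⁵ pairs on 36 samples) the t approximation
is accurate and orders of magnitude cheaper than exact enumeration; being
rank-based, the screen needs no prior standardisation of the environmental
variables. All tested pairs form **one** BH-FDR family — separating families
would make the OTU–environment edges incomparable with the OTU–OTU edges.

Edges require `|rho| > 0.7` **and** `q < 0.01`, both strict, matching the
printed inequalities of the thresholds. Nodes left without edges are dropped
from the graph but counted, so the report still reflects the screened
universe.

Topology: betweenness is Brandes' algorithm on unweighted shortest paths
with unnormalised pair counts (the test suite checks it against exhaustive
path enumeration on all small graphs); closeness uses the Wasserman–Faust
component-wise form scaled by component reach, so disconnected graphs do not
produce infinities; eigenvector centrality is a deterministic power
iteration on the largest component, max-normalised (a deterministic start
vector keeps reruns byte-identical, which ARPACK's random start would not).
The clustering coefficient is the mean local clustering over nodes of degree
≥ 2: for a G(n, m) random graph its expectation is the edge probability
m/(n(n−1)/2), which is the property the null-model comparison relies on;
zero-imputing degree-<2 nodes would bias the mean downward by the fraction
of low-degree nodes. Average path length and diameter are computed on the
largest connected component, reported with the component coverage fraction.

The module partition uses deterministic greedy agglomerative modularity
maximisation. Determinism was preferred over stochastic alternatives
(e.g. Louvain) because the pipeline promises byte-identical reruns; on
graphs with the planted-module structure the two agree.

The null model is G(n, m): 1,000 Erdős–Rényi graphs with exactly the
observed node and edge counts, each summarised by the same topology
function, yielding a mean, SD and z-score per metric. A fixed-m construction
makes the ensemble's average degree exactly 2m/n in every replicate — a
useful built-in self-check.

Keystones are the top-k (default 10) OTU nodes by betweenness, ties broken
by degree then node id; environmental variables are excluded from the
ranking since they cannot be keystone taxa.

## Indicator species

For OTU abundances split into groups, specificity `A_g` is the group mean
divided by the sum of group means — the group-size-corrected form, which is
robust to the unequal group sizes that arise when seasons are pooled —
and fidelity `B_g` is the within-group occurrence fraction;
`IndVal_g = sqrt(A_g · B_g)`. The classic total-abundance specificity is a
one-line variant and intentionally not the default.

The permutation test fixes each OTU's observed best group and recomputes the
IndVal of **that** group under label permutations. The alternative — taking
the maximum over groups in each permutation — asks a subtly different
question ("is this OTU a perfect indicator of *some* group?") and, for a
perfect two-group indicator on 3+3 samples, counts the complementary
labelling as equally extreme, doubling the exact p. The fixed-group
statistic gives the exhaustive-enumeration answer 1/20 on that design, which
the test suite verifies; Monte-Carlo p-values use the add-one estimator and
are BH-corrected across OTUs only (one best group is tested per OTU).
Selection requires `indval > 0.85` and `q < 0.05`.

The pipeline tests the network's OTU nodes by default (the indicator
question is asked of the taxa that structure the community); testing all
abundance-filtered OTUs is a config switch (`indval_scope = "abundant"`),
and the acceptance script uses it so that recovery is measured against every
planted indicator.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated: 3 seasonal groups (May, August, November) × 12 samples; seven
environmental covariates (DOC, DO, ORP, EC, pH, PWT, WT) drawn as Gaussians
from per-month mean ± SD profiles typical of a subalpine peatland campaign
(warm, wet May/August vs cold, oxidised November); 600 OTUs at a sequencing
depth of ~40,205 reads.

OTU abundances are log-normal: a per-OTU baseline `mu_i ~ N(0, 1.5)` plus a
per-sample deviation with SD 0.8. Four planted modules of 8 OTUs share a
latent Gaussian factor so that every within-module pair has latent
correlation 0.9; module OTUs get an elevated baseline (log-mean 1.5) so they
clear the 0.1% abundance filter with low counting noise. Five indicator
OTUs per group are multiplied by 8 in their group and divided by 8
elsewhere (`indicator_fold = Inf` plants presence/absence indicators).
Counts are a multinomial draw per sample at Poisson(depth) — the data are
compositional, as rarefied counts are; a negative-binomial per-OTU
alternative is available. Module–environment coupling is **off by default**:
it keeps the planted correlation structure and the planted indicators
orthogonal, so each recovery score measures one thing. Coupling a module to
a covariate (`env_link`) is supported for studying environmentally driven
modules.

Plate series follow logistic colour development
`C(t) = Cmax/(1 + exp(−r(t − t_mid)))` per substrate with guild-specific
`Cmax` encoding the observed preference order (esters 1.8 > amino acids 1.6
> amines 1.5 > carbohydrates 1.2 > carboxylic acids 1.0 > alcohols 0.6, OD
units), `t_mid` placed a quarter of the way from the 24 h lag to the 168 h
plateau (60 h), and the rate scaled by `exp(0.04·(PWT − 15))` — warmer pore
water develops colour faster, which is what makes the 72-h AWCD contrast
between warm and cold groups reproducible. Control wells develop a faint
colour (`Cmax = 0.005`) with the same kinetics, so the blank-corrected
response is exactly `(Cmax − 0.005)·σ(t)` and noiseless AWCD curves are
monotone. Read noise is additive Gaussian (SD 0.01 OD) at both wavelengths.

What the generator does **not** emulate: compositional correlation bias
(negative correlations induced by the simplex constraint are weak at 600
OTUs but real at low richness), taxonomy, chimeras and sequencing error,
OTU-abundance zero inflation beyond the multinomial, temporal
autocorrelation between months, and plate-reader drift or edge effects.
Passing recovery tests therefore demonstrates that the statistical machinery
recovers the structure it targets under a faithful null — not that every
real-data artefact is handled.

## Numerical choices and degenerate inputs

- Permutation p-values everywhere use `(count + 1)/(n_perm + 1)` and every
  stochastic stage takes an explicit seed; the pipeline derives stage seeds
  from one master seed, and no output file contains a timestamp, so reruns
  are byte-identical.
- Snapshot selection: exact time, else the nearest reading within ±6 h,
  else an error; linear interpolation is opt-in.
- All-zero plates, constant covariates, constant distance matrices,
  all-absent OTUs and empty edge sets raise informative errors (the network
  error reports the closest near-miss pair) instead of propagating NaN.
- Keystone ties break by degree then lexicographic id, so rankings are
  stable across platforms.
- Eigenvector centrality iterates to `1e-12` with a uniform start; PCoA
  tolerates negative eigenvalues to `1e-10` of the largest before they are
  deemed meaningful.

## Problem sizes used in the test suite

Unit tests run on toy objects (≤ 40 samples, ≤ 120 OTUs). The
property-style checks use 1,000 random plates, 50 random small graphs
against the exhaustive betweenness oracle, a 1,000-replicate G(100, 200)
ensemble, 500-replicate type-I-error simulations for PERMANOVA and
Kruskal–Wallis, and 20 seeds of the default 36-sample × 600-OTU scenario for
module and indicator recovery — sizes at which each check is decisive while
the whole suite stays desk-scale.

## Known limitations

- Spearman screening is not compositionality-aware; on low-richness data a
  dedicated compositional method would be preferable.
- The null ensemble is G(n, m); degree-preserving (configuration-model)
  nulls are out of scope.
- PERMANOVA is the one-way design without strata or covariates.
- The degree power-law check is a least-squares log–log fit, a descriptive
  diagnostic rather than a maximum-likelihood tail estimate.
- CLPP kinetic parameters are not estimated from the plate series (no
  logistic/Gompertz fitting); the snapshot analysis is the contract.
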