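---
title: "Methods: community ecology of soil protist counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community ecology of soil protist counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protistecol)
```

This vignette documents the models behind `protistecol`, the choices made
where the methodology was genuinely open, and what the package's synthetic
data can and cannot tell you about real surveys.

## The data model

The central object is an `abundance_table`: a samples × species matrix of
non-negative morphospecies counts with optional per-sample metadata
(ecosystem, season, decimal-degree coordinates, altitude). Counts are
individuals enumerated from soil cultures, so a blank or zero cell is a
true absence, not a missing value; files are read accordingly. Taxonomy is
a strict four-rank lineage (genus, family, order, class) validated for
internal consistency — a family may belong to only one order, an order to
only one class. Environmental tables carry soil water content (SWC, % by
mass), pH, total nitrogen and organic matter (g/kg), available phosphorus
and potassium (mg/kg), surface temperature (°C) and altitude (m); missing
environmental values are allowed and propagate as pairwise exclusion, never
as imputation.

## Diversity and bioindication

Shannon–Wiener diversity is computed in natural logarithms,
$H = -\sum_i (n_i/N)\,\ln(n_i/N)$, and Margalef richness as
$D = (S-1)/\ln N$ with $D = 0$ at $N = 1$ by convention. Group-level values
default to means of per-sample indices, the convention of the soil-protist
literature; recomputation on the pooled community is available via
`pooled = TRUE` because the two differ whenever sample totals vary.

The C/P quotient is the ratio of Colpodea to polyhymenophoran
(Spirotrichea + Heterotrichea + Armophorea) species. The default basis is
species richness — the quotient is then invariant to abundance rescaling —
with an abundance basis available because bioindication usage varies. A
zero denominator yields an explicit "undefined" flag rather than infinity.
Quotients at or below 1 are read as a relatively benign soil habitat.

Group comparisons offer ordinary one-way ANOVA with Tukey HSD, and a
permutation alternative (omnibus F plus pairwise mean differences,
Benjamini–Hochberg adjusted) recommended at the small per-group sample
sizes typical of such surveys. The permutation route's type-I error at
α = 0.05 is verified to sit in [0.035, 0.065] over 1000 null simulations.

## β diversity

Bray–Curtis dissimilarity is computed on raw counts by default; a
`relativize` flag divides samples by their totals first, since survey
reports rarely state which was used. NMDS uses Kruskal stress-1 with
monotone regression (`vegan::monoMDS`), k = 2, and a best-of-restarts
strategy: the first start is the metric-scaling configuration, the rest are
random, and the lowest-stress solution is kept; everything is deterministic
under the seed. One subtlety: with heavily tied dissimilarities (e.g. a
regular simplex), primary tie treatment allows monotone regression to fit
perfectly, so stress 0 is then correct, not a failure.

Group separation is tested by one-way PERMANOVA — Anderson's pseudo-F on
the squared-dissimilarity partition — with the exact permutation p-value
$(1 + \#\{F_\pi \ge F\})/(1 + n_\pi)$. The pseudo-F is cross-checked
against `vegan::adonis2` in the test suite; the permutation engine is the
package's own so that seeding and tie handling are fully specified.

## Co-occurrence networks

Correlation thresholds for such networks are rarely published. The
defaults follow common practice in the microbial-network literature:
Spearman correlation on counts pooled per scope, |r| ≥ 0.6,
Benjamini–Hochberg adjusted p ≤ 0.05, and a prevalence floor of presence
in ≥ 3 samples; all are exposed as arguments. Correlation p-values use the
t approximation $t = r\sqrt{(n-2)/(1-r^2)}$ for both coefficients.
Isolated species are dropped; constant species cannot be correlated and
are dropped with a warning.

Modules are found by greedy modularity maximisation (deterministic;
Louvain optional under a seed) on |r| weights, ignoring sign. The topology
panel reports average degree 2E/N, density 2E/(N(N−1)), mean local
clustering with nodes of degree < 2 contributing zero, mean shortest-path
length over connected pairs only (fragmented graphs then still yield a
finite value), and the signed-edge percentages.

Node roles use the Guimerà–Amaral conventions: the within-module degree
z-score standardises a node's links into its own module against its module
mates, while the participation coefficient divides by the node's **total**
degree. The two uses of "degree" are deliberately different and not
configurable, to keep roles comparable with the wider literature. Role
thresholds are strict (> 2.5, > 0.62), so boundary-equal values fall in
the lower category; connectors, module hubs and network hubs are the
keystone candidates. The implementation is verified against brute-force
adjacency enumeration on 100 random graphs of up to 12 nodes at 1e-12.

## Environmental drivers

Mantel tests correlate off-diagonal dissimilarities and permute one
matrix's rows and columns jointly; the p-value is one-sided. Environmental
distance is the absolute per-factor difference, one matrix per factor,
matching the per-factor panels of survey reports; a combined z-scored
Euclidean distance is deliberately not the default. Geographic distance is
haversine with Earth radius 6371 km. Distance-decay regressions are
ordinary least squares on pairwise values, but significance comes from
Mantel-style permutation rather than the t distribution, because pairwise
dissimilarities sharing a sample are not independent — parametric p-values
on such regressions are anti-conservative.

## The neutral community model

For a species with metacommunity mean relative abundance $p$, the Sloan
model predicts its occurrence frequency across local communities of size
$N$ (taken as the mean per-sample total) from a beta law with shape
parameters $Nmp$ and $Nm(1-p)$. The classical fit evaluates
$1 - \mathrm{BetaCDF}(d;\,Nmp,\,Nm(1-p))$ at a detection limit $d = 1/N$.
That threshold form is a continuous approximation: when each local
community really is a finite draw of $N$ individuals, a species can be
detected even though its latent frequency lies below $1/N$. The package
therefore defaults to the exact finite-sample detection probability under
the same beta law,

$$F(p) = 1 - \frac{B(Nmp,\; Nm(1-p) + N)}{B(Nmp,\; Nm(1-p))},$$

the zero-truncation of the beta-binomial. On Dirichlet-multinomial count
data the threshold form overestimates $m$ systematically (about 25% at
$m = 0.1$, $N = 1000$), while the exact form is unbiased to within a few
percent; both are available via the `detection` argument, and the
recovery behaviour is part of the test suite. $m$ is estimated by
unweighted least squares in frequency space — a coarse log-spaced grid
followed by Levenberg–Marquardt — with an asymptotic 95% Wald interval.
R² = 1 − SS\_res/SS\_tot may legitimately be negative and is never
clamped. The 95% envelope is the Wilson score interval of the predicted
frequency at the realized number of samples; species fall below, within or
above it, and the within-fraction is the usual summary of how far
stochastic dispersal alone explains assembly.

## The synthetic community generator

The generator emulates the design of a plateau river-basin survey: 19
sites allocated 4/5/5/5 to grassland, farmland, wetland and sea-buckthorn
forest, three seasons redrawn independently, local communities of exactly
1000 individuals, and a 200-species metacommunity. The metacommunity
species-abundance distribution is a log-series (Fisher's α solved so the
target richness is reached at the realized survey size; log-normal
optional). Local communities are Dirichlet-multinomial draws with
Dirichlet weights $Nm\,p_i$ — the stationary Sloan/Hubbell approximation —
rather than explicit birth–death simulation: this matches the
beta-distributed frequencies the neutral fit assumes and is orders of
magnitude faster.

Environmental filtering, when enabled, gives each species a uniform niche
optimum on the SWC axis and weights the metacommunity by
$\exp(-w\,((\mathrm{SWC}-u)/\mathrm{range})^2)$ before renormalisation;
$w = 0$ reduces exactly to the neutral draw under the same seed (the two
generators consume identical RNG substreams). Habitat SWC ranges are
non-overlapping by default, with wetland highest — the qualitative
gradient such basins show — and the remaining factors are drawn uniformly
within field-plausible ranges and left uncoupled from composition, so they
serve as negative controls in driver analyses. All randomness flows from
the single scenario seed through derived substreams; there is no hidden
global state.

What the generator does **not** emulate: spatial autocorrelation of
composition beyond the SWC gradient, temporal carry-over between seasons
(seasons are independent redraws), variable sequencing-style sample
depths (totals are exact), taxonomic structure in co-occurrence, and
compositional artefacts of relative-abundance data. Passing tests on
synthetic data therefore validate the arithmetic and the statistical
calibration of each stage, not the ecological fidelity of any particular
field inference.

## Problem sizes and numerical choices

The test and acceptance experiments use survey-scale problems chosen as
the package's own calibration conditions: neutral-recovery experiments at
m = 0.1, N = 1000, 60 samples × 150 species over 20 replicates;
Mantel/PERMANOVA calibration at n = 15 samples, 99 permutations, 1000 null
simulations; network oracles on graphs of 5–12 nodes. Permutation p-values
always use the add-one form and so never reach zero. Percentages intended
to reproduce printed tables are rounded half-up to two decimals, since
base R's round-half-even produces occasional one-digit discrepancies
against published tables.

## Known limitations

Only one-way PERMANOVA is provided; no PCoA/CCA/RDA, no partial Mantel or
variation partitioning, no compositional corrections (SparCC-style) for
the networks, and no Chao/ACE/Simpson estimators — the pipeline covers the
analyses of the survey genre it targets, not the full ordination
toolbox. The neutral fit treats samples as exchangeable local communities;
nested or longitudinal designs would need a hierarchical extension.
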