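# protistecol

Community-ecology analysis of soil protist (ciliate) morphospecies counts.

Soil ciliates are single-celled, cilia-bearing protists that are cultured
from soil samples, identified morphologically and counted individual by
individual. Surveys of this kind — a handful of sites per habitat, a few
seasons, a couple of hundred morphospecies — ask a recurring set of
questions: how is the fauna composed taxonomically, how diverse is each
habitat and season, do communities differ in composition, which species
co-occur and which hold the co-occurrence network together, which soil
factors drive turnover, and how much of community assembly is explained by
stochastic dispersal alone. `protistecol` implements that whole pipeline for
sample × species count tables, together with a seeded synthetic-community
generator so that every stage can be exercised and calibrated without field
data.

## What it computes

* **Composition** — species counts and percentages per genus / family /
  order / class, and exhaustive shared/exclusive species partitions across
  ecosystems or seasons (UpSet-style).
* **α diversity** — Shannon–Wiener H = −Σ (nᵢ/N) ln(nᵢ/N) (nats) and
  Margalef richness D = (S−1)/ln N per sample, with group means and
  ANOVA/permutation comparisons.
* **C/P quotient** — the bioindication ratio of Colpodea to
  "polyhymenophoran" (Spirotrichea + Heterotrichea + Armophorea) species;
  C/P ≤ 1 indicates a relatively benign, stable soil habitat.
* **β diversity** — Bray–Curtis dissimilarity d(x,y) = Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ),
  NMDS ordination (Kruskal stress-1, random restarts), and PERMANOVA with
  exact permutation p-values.
* **Co-occurrence networks** — Spearman/Pearson correlation networks with
  |r| and adjusted-p thresholds, modularity-based module detection, and the
  standard topology panel (average degree 2E/N, density, clustering, mean
  path length, signed-edge ratios).
* **Keystone species** — within-module degree z-score Zᵢ and participation
  coefficient Pᵢ = 1 − Σₛ(Kᵢₛ/kᵢ)², with the classical role thresholds
  (Zᵢ > 2.5, Pᵢ > 0.62) separating peripherals, connectors, module hubs and
  network hubs.
* **Environmental drivers** — Mantel tests of community distance against
  per-factor environmental distance, haversine geographic distances, and
  permutation-tested distance-decay regressions.
* **Community assembly** — the Sloan neutral community model: occurrence
  frequency predicted from mean relative abundance via a beta law with
  shape Nm·p, fitted by least squares, with R², a 95% envelope, and
  per-species above/within/below partitions.

## Worked example

The package ships the family-level inventory of a Tibetan-plateau river
basin ciliate survey as a built-in fixture, and a generator whose defaults
mirror that survey's design (19 sites in four habitats × three seasons,
1000 individuals per local community, 200-species log-series
metacommunity).

```r
library(protistecol)

tb <- composition_to_tables(composition_fixture())
head(summarize_composition(tb$abundance, tb$taxonomy, rank = "order"), 3)
#>          taxon species_count percent
#> 1    Haptorida            35   17.59
#> 2    Sessilida            19    9.55
#> 3 Prorodontida            18    9.05

cp_quotient(tb$abundance, tb$taxonomy)[, 3:6]
#>   colpodea polyhymenophora  quotient verdict
#> 1       14              43 0.3255814    good
```

Haptorida dominates the inventory (35 of 199 species, 17.59%), and the
whole-survey C/P quotient of 14/43 ≈ 0.33 ≤ 1 indicates a relatively benign
soil environment.

```r
scn <- sim_scenario(env_filter_strength = 6, seed = 1)
sim <- simulate_filtered(scn)

fit_ncm(sim$abundance)
#> Sloan neutral community model fit
#>   scope: all (57 samples, 168 species)
#>   m = 0.0653  Nm = 65.3  N = 1000.0  R2 = 0.942
#>   species within / below / above envelope: 76.8% / 13.7% / 9.5%

d <- bray_curtis(sim$abundance)
nmds(d, restarts = 20, seed = 1)
#> NMDS ordination: 57 samples in 2 dimensions
#>   stress (Kruskal stress-1): 0.1025

permanova(d, sim$abundance$metadata$ecosystem, n_perm = 999, seed = 1)
#> PERMANOVA: pseudo-F(3, 53) = 18.056, p = 0.001 (999 permutations)

mantel_env(d, sim$env, c("SWC", "pH"), n_perm = 999, seed = 1)
#>   factor          r     p  n
#> 1    SWC 0.93393686 0.001 57
#> 2     pH 0.05434085 0.096 57
```

On this filtered survey the habitats separate cleanly in Bray–Curtis space
(low stress, PERMANOVA p = 0.001), soil water content — the factor the
generator couples to composition — carries a strong Mantel signal while pH
does not, and the neutral fit still absorbs much of the occurrence
structure (R² = 0.94) while the environmental filter depresses migration
(m̂ = 0.065 against a generating m = 0.1). A strictly neutral survey of the
same size fits better and recovers m within a few percent.

The full pipeline (all stages, per-stage TSVs, one results JSON) runs from
a config:

```r
run_pipeline(list(abundance = "abundance.csv", metadata = "metadata.csv",
                  env = "env.csv", group_by = "ecosystem",
                  seed = 1, out_dir = "results"))
```

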