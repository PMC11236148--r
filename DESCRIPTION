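Package: protistecol
Title: Community Ecology of Soil Protist Morphospecies Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for sample-by-species count tables of soil
    protist (ciliate) morphospecies: taxonomic composition summaries and
    shared-species partitions, Shannon and Margalef alpha diversity, the
    Colpodea/polyhymenophora (C/P) bioindication quotient, Bray-Curtis beta
    diversity with non-metric multidimensional scaling and PERMANOVA,
    correlation-based co-occurrence networks with topology panels and
    Zi-Pi keystone classification, Mantel tests and distance-decay
    regressions against environmental and geographic distance, and fitting
    of the Sloan neutral community model to occurrence-frequency data.
    Includes a seeded synthetic community generator (neutral
    Dirichlet-multinomial sampling with optional environmental filtering
    along a soil-water-content gradient) so every stage can be exercised
    and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    geosphere,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
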