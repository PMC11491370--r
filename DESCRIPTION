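Package: strepniche
Title: Resource-Use Niche, Inhibition and Phylogenetic Analysis of Soil
    Streptomyces Phenotype Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for hierarchical soil Streptomyces phenotype
    experiments in which a foliar-fungicide treatment is nested within
    plant-richness plots. Quantifies carbon-source utilisation phenotypes
    from 95-substrate phenotype-array plates (niche width, growth
    efficiency, and an asymmetric pairwise niche-overlap statistic),
    dilution-plate densities and inhibitory fractions from indicator-strain
    overlays, and disk-diffusion antibiotic-resistance zones. Compares
    isolate communities phylogenetically with Faith's phylogenetic
    diversity, unweighted UniFrac distances and PERMANOVA, and provides the
    matching statistical layer: nested analysis of variance, Tukey HSD with
    compact letter displays, Pearson correlations, and per-substrate tests
    with Benjamini-Hochberg or Benjamini-Yekutieli false-discovery-rate
    control. A seeded synthetic-data generator reproduces the experiment's
    hierarchical structure with configurable treatment effects so the whole
    pipeline can be exercised and calibrated without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
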