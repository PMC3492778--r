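Package: isopair
Title: Sexual Isolation Indices, Cuticular Hydrocarbon Profiles and
    Desiccation Survival for Pairwise Mate-Choice Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistics for pairwise premating-isolation studies in
    insects. Estimates pair sexual isolation (PSI) and pair total (PTI)
    coefficients and the joint isolation index I_PSI from 2x2 mate-choice
    contingency tables, with multinomial bootstrap standard deviations and
    two-tailed significance tests. Converts per-fly gas-chromatography
    peak areas into absolute (ng/fly) and relative cuticular hydrocarbon
    profiles against an internal standard, and analyses them with
    compositional log-contrasts, arcsine-square-root transforms, per-
    hydrocarbon one-way ANOVA with Tukey HSD, phenotype ratios and percent
    differences. Builds survival curves from mortality counts recorded on
    a fixed inspection grid and estimates the median survival duration
    with bootstrap confidence intervals. Seed-reproducible generators for
    mate-choice trials, Dirichlet-structured hydrocarbon compositions and
    gridded death records allow every stage to be exercised without
    external data. Bundled fixtures cover a three-strain Drosophila
    simulans pheromone-polymorphism study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: StatisticalMethod, Metabolomics, Survival, ExperimentalDesign
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'datasets.R'
    'desiccation.R'
    'hc-profiles.R'
    'io.R'
    'isopair-package.R'
    'latency.R'
    'mating-stats.R'
    'show-methods.R'
    'synth.R'
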