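Package: tetradMA
Title: Mutation Accumulation Dynamics Under Intra-Tetrad Mating in Diploid Yeast
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing diploid Saccharomyces cerevisiae mutation
    accumulation lines propagated through alternating vegetative growth and
    single-tetrad meiotic bottlenecks. Provides exact tetrad-segregation and
    intra-tetrad mating models with analytic fixation/loss/heterozygosity
    probabilities, a forward Monte-Carlo simulator of base-substitution
    accumulation under vegetative and meiotic bottleneck regimens, per-base
    per-division mutation-rate estimators with spore- and meiosis-specific
    corrections, an empirical lower-tail P-value scan for the upper limit of the
    meiotic mutation rate, analysis of drug-marker intra-tetrad mating assays
    with a crossover misclassification correction, Perkins map distances from
    tetrad class counts, and synthetic-data generators with known ground truth
    for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, Software, StatisticalMethod
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'tetrad-genetics.R'
    'bottleneck-sim.R'
    'mating-assay.R'
    'synthetic-data.R'
    'rate-inference.R'
    'constructors.R'
    'io.R'
    'commands.R'
    'methods.R'
    'tetradMA-package.R'
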