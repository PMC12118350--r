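Package: admixscreen
Title: Simulation-Based Evaluation of qpAdm Admixture Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for measuring how reliably high-throughput qpAdm
    admixture screens recover true admixture histories. Provides two
    synthetic-genotype generators (random dated admixture graphs and
    hexagonal stepping-stone landscapes, both simulated with the msprime
    coalescent engine and degraded to ancient-DNA quality), a block-jackknife
    f-statistics and qpWave/qpAdm inference core, the four screening
    protocols (distal/proximal x rotating/nonrotating) with the full grid of
    36 composite model-feasibility criteria, and an evaluation layer that
    scores models by spatial optimality metrics (source-target distances,
    source-target-source angles), classifies admixture-graph models into
    false and true positives by topological rules, and summarises screens as
    prestudy odds, false discovery rates and related error rates, including
    a great-circle variant for published model tables with real coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    geosphere,
    testthat (>= 3.0.0)
SystemRequirements: python (>= 3.8) with msprime, numpy
Config/testthat/edition: 3
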