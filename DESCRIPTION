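Package: preyscale
Title: Predator-Prey Body-Mass Scaling in Carnivorous Mammals by Phylogenetic GLS
Version: 0.1.0
Authors@R:
    person("preyscale", "maintainers", email = "maintainers@preyscale.org", role = c("aut", "cre"))
Description: Tools for analysing how the minimum, maximum and range of prey
    body mass scale with predator body mass across carnivorous mammals while
    accounting for shared evolutionary history. Implements phylogenetic
    generalized least squares (PGLS) with maximum-likelihood estimation of
    Pagel's lambda, AICc model selection among nested environment-by-mass
    models over ensembles of stochastically resolved dated phylogenies,
    taxonomic variance-components decomposition, and descriptive moments of
    prey-mass distributions. Includes a birth-death tree and trait simulator
    so the entire pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
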