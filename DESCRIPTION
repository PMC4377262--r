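Package: margadapt
Title: Local-Adaptation Inference for Depth-Structured Coral Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for detecting potential local adaptation
    between shallow and mesophotic populations of sessile marine invertebrates
    from microsatellite genotypes and transplant/common-garden phenotypes.
    Implements GENEPOP input/output, per-sample diversity statistics (observed
    and unbiased expected heterozygosity, Weir-Cockerham f with permutation
    tests, rarefied allelic richness), Weir-Cockerham theta with bootstrap
    confidence intervals over loci, genotypic differentiation tests, Nei et
    al. (1983) Da distances with neighbor-joining phenograms, the linkage-
    disequilibrium estimator of contemporary effective population size with
    Waples' bias correction and jackknife confidence intervals, univariate
    permutational ANOVA on Euclidean distance, and the P_ST-F_ST comparison
    with (c/h^2)_crit sensitivity analysis. A synthetic-data module generates
    island-model genotypes and structured phenotypes so that the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
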