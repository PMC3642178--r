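Package: oxbowflow
Title: Testing Meander-Loop-Cutoff Mediated Gene Flow Across a Riverine Barrier
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to test whether meander loop cutoff (the natural severing of
    a river meander, which passively transfers resident organisms to the
    opposite bank) promotes gene flow across a riverine barrier. Provides a
    forward-time two-bank metapopulation simulator with a cutoff transfer
    event, readers and writers for GENEPOP/STRUCTURE/FASTA study data,
    diversity and differentiation statistics (Nei gene diversity,
    Weir-Cockerham F-statistics, Hedrick's G'ST, Jost's D), Hardy-Weinberg and
    linkage-disequilibrium tests, a Bayesian admixture clustering sampler with
    Evanno K selection, an assignment-based recent-migration MCMC, the
    private-alleles Nm estimator, a mixed-logit comparison of historical
    versus current river channels as predictors of private-allele
    distributions, and a battery that scores the seven predictions of
    cutoff-mediated dispersal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
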