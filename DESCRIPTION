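Package: admixscreen
Title: Supervised Continental Ancestry Estimation for Carrier Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Supervised admixture-proportion estimation for clinical carrier
    screening cohorts. Estimates per-individual continental ancestry
    proportions by expectation-maximization against a fixed panel of
    population allele frequencies, selects ancestry-informative markers by a
    two-stage Wright's Fst ranking over continental-mean frequencies (with
    call-rate, coverage and LD-pruning QC), and provides the downstream
    clinical statistics: paired self-reported-ethnicity concordance with
    exact McNemar tests, ancestry-stratified carrier rates with Fisher's
    exact and Mann-Whitney tests, and residual carrier risk after a negative
    screen under a given detection rate. A model-matched simulator generates
    frequency panels, admixed genotype cohorts and sample metadata for
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
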