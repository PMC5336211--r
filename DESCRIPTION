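Package: glandabc
Title: Gland-Fission Tumor Simulation and ABC Inference of Mutation and
    Stem-Cell Division Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates colorectal tumor growth as a three-phase gland
    process (formation of the first gland, exponential gland fission,
    and a constant-size phase driven by cancer stem cell division),
    embedding Poisson point mutations at every cell division.  Couples
    the simulator to rejection-based Approximate Bayesian Computation
    with weighted summary statistics to estimate the point-mutation
    rate before and after first-gland formation (a test for an early
    mutation burst) and the asymmetric-division probability of cancer
    stem cells from single-gland sequencing data.  Includes a
    negative-binomial/binomial sequencing noise model, an exact
    binomial fixation test, summary statistics for multi-gland variant
    tables, equal-weight, local- and global-regression statistic
    weighting schemes, scripted parameter-recovery studies, and a
    reader for MuTect call-stats files with copy-number-adjusted
    allele frequencies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
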