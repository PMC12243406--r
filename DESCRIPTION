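Package: targetmr
Title: Multi-Omics Mendelian Randomization for Drug-Target Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a cis-QTL Mendelian randomization (MR) pipeline for
    prioritising druggable genes from GWAS summary statistics: harmonisation of
    exposure and outcome summary data, cis-instrument selection with LD
    clumping, Steiger directionality and instrument-strength filters, Wald
    ratio and inverse-variance-weighted causal estimation with MR-Egger
    intercept diagnostics, summary-data-based MR (SMR) with the HEIDI test for
    distinguishing pleiotropy from linkage, Bayesian colocalisation over five
    hypotheses using Wakefield approximate Bayes factors, a three-tier evidence
    classifier for candidate targets, endophenotype MR and phenome-wide MR
    scans with false-discovery-rate control. A summary-statistics simulator
    generates LD-structured cis-QTL loci and binary or quantitative outcomes
    under controlled causal architectures so that every pipeline stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
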