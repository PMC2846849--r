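Package: mitoburden
Title: Mitochondrial DNA Variant Annotation and Case-Control Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing mitochondrial DNA variation in small
    case-control cohorts: a circular mitogenome model with the embedded
    rCRS (NC_012920) gene layout, codon-level annotation under the
    vertebrate mitochondrial genetic code, global pairwise alignment and
    variant calling for amplicon-scale sequences, synonymous /
    non-synonymous and OXPHOS-complex classification, novelty flagging
    against a known-variant catalogue, threshold-based pathogenicity and
    ROS/LHON screening, and per-gene carrier-collapse burden statistics
    (exact Fisher tests by hypergeometric enumeration, Pearson chi-square,
    cohort relative risks with Katz confidence intervals).  A seeded
    synthetic-data generator produces circular genomes, cohorts with
    planted variants and score files with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
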