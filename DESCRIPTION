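Package: haplogic
Title: Genic Haplotype Association Discovery with Logic-Regression Trees
Version: 1.0.0
Authors@R:
    person(given = "Package", family = "Author",
           email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of genic haplotype associations in phased
    case-control cohorts. Searches gene-centered analytic windows (gene span
    plus 500-kb flanks, LD-pruned to tagging SNPs) for three-SNP Boolean
    haplotype trees with a simulated-annealing logic-regression search over
    chromosome-level logistic deviance, ranks windows with a permutation-based
    evaluation statistic built from leave-one-out medians and the median
    absolute deviation, and carries selected haplotypes through an additive
    copy-count logistic model with Bonferroni-corrected replication. Includes
    the standard sliding-window benchmark (EM haplotype frequency estimation
    with a global score test that accounts for phase uncertainty), Fisher
    exact enrichment of haplotype SNPs over annotation interval tracks and
    eQTL indicator tables, SHAPEIT HAPS/SAMPLE and phased-VCF input with the
    usual variant and sample quality-control filters, and a phased-cohort
    simulator with configurable allele frequencies, adjacent-SNP linkage
    disequilibrium, and an embedded Boolean-tree risk effect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
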