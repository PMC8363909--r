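Package: plasmafrac
Title: Sequential Size- and Density-Based Blood Plasma Fractionation Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative accounting and omics statistics for sequential
    size-exclusion chromatography (SEC) and density-gradient fractionation of
    blood plasma used to separate extracellular vesicles (EV) from lipoprotein
    particles (LPP). Provides recovery, enrichment and depletion metrics across
    fractions; a Perseus-style label-free proteomics workflow (valid-value
    filtering, down-shifted normal imputation of missing-not-at-random values,
    S0-moderated two-sample tests with permutation-based FDR, correlation, PCA
    and hierarchical-clustering summaries); rule-based catalogues of putative
    non-EV-associated proteins and EV-corona candidates; a small-RNA arm
    (median-of-ratios normalization, a simplified negative-binomial Wald test,
    biotype composition, tRNA codon-usage fold-change profiles, classic-ES
    permutation gene-set enrichment, exact Mann-Whitney tests); and a seeded
    synthetic plasma/fractionation/omics generator so every stage is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
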