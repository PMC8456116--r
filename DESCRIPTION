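Package: incoloc
Title: Integrative Co-Localization of SNV and CNV Association Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint region-based association testing of single nucleotide
    variants (SNVs) and copy-number variation (CNV) segments mapped to the
    same gene or genomic window. Implements a two-stage integrative
    co-localization analysis: a gene-level screen using an optimal weighted
    kernel score test (SKAT-O family) on the combined cross-platform marker
    matrix under a generalized linear model null, followed by a moving-window
    scan that co-localizes the concurrent SNV-CNV signal within screened
    genes. Also provides the traditional union-union and intersection-union
    parallel integration baselines, quality control (missingness and exact
    Hardy-Weinberg filtering), readers for PLINK-style, VCF and BED-like
    inputs, and a case-control simulation harness with false-positive,
    power and specificity metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, yaml, jsonlite, vcfR
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
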