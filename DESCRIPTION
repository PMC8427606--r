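Package: mirsmr
Title: Summary-Data Mendelian Randomization for MicroRNA Risk Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transcriptome-wide association analysis of microRNA expression
    and disease risk from GWAS and cis-eQTL summary statistics. Implements
    allele harmonization of summary tables against an LD reference, the
    summary-data Mendelian randomization (SMR) ratio-of-effects test with a
    single cis-eQTL instrument, the HEIDI heterogeneity test separating
    pleiotropy/causality from linkage, Benjamini-Hochberg FDR control and
    sign-based oncogenic/tumor-suppressive role calls, a simplified
    negative-binomial tumor-versus-normal differential-expression stage with
    MA classification, a three-database miRNA target-consensus filter, and a
    synthetic-data generator producing paired GWAS/eQTL summary statistics
    under pleiotropy, causality and linkage models for testing every stage
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
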