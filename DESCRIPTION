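Package: hlabias
Title: Population and Income Bias Audits for Peptide-HLA Binding Data and
    Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well peptide-HLA (pHLA) binding datasets represent
    geographic populations and how evenly binding predictors perform across
    HLA alleles. Ingests allele-frequency tables in the style of the Allele
    Frequency Net Database, classifies populations by World Bank national
    income level, and computes population coverage under Hardy-Weinberg
    genotype sampling (coverage, PC90 and the scaled sPC90 statistic).
    Provides multi-allelic deconvolution of mass-spectrometry data, proteome
    decoy sampling, and per-allele predictor accuracy metrics (positive
    predictive value and fraction of observed peptides), together with
    income-stratified significance tests (one-way ANOVA, one-sided
    Kolmogorov-Smirnov) and a synthetic-data generator so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
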