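Package: emqtlscan
Title: Expression-Methylation QTL Screening Around Transcription Factor
    Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcription factors whose expression correlates
    with DNA methylation specifically around their own binding sites
    ("emTFs") from paired tumour expression and methylation cohorts. The
    screen computes Spearman expression-methylation correlations for every
    TF against every variable CpG, applies Bonferroni control, measures the
    enrichment of correlated CpGs within 200 bp of each TF's binding sites
    with Mann-Whitney U tests, and calls TFs that recur across cohorts.
    Downstream stages partition correlated CpGs by sign, contrast the TF
    binding signatures of correlated versus methylation-protected CpGs,
    link CpGs to candidate target genes with an anti-correlation filter,
    and classify TFs by tumour-purity and chromatin-accessibility context.
    A seeded multi-cohort simulator with planted effects supports
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
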