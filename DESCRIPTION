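Package: mircascade
Title: Prioritisation of Transcription-Factor-Regulated miRNAs from ChIP
    Binding and Tumour Expression Strata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for identifying microRNAs whose
    transcription is controlled by a pluripotency transcription factor in
    germ cell tumours. Combines consensus ChIP-seq peak calling across
    replicates, strand-aware assignment of peaks to graded upstream windows
    of miRNA loci, driver-gene expression stratification with differential
    miRNA expression, cross-cohort direction-consistency filtering against
    tumour-versus-normal fold changes, a genomic-class-specific
    TSS-distance rule, clinical covariate association, and downstream
    target-consensus, cytoband and delta-delta-Ct analyses. Ships a
    synthetic-data generator with planted ground truth so the whole
    cascade is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
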