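Package: editomeR
Title: RNA:DNA Difference Calling and Editome Analysis for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects RNA editing events (RNA:DNA differences, RDDs) from
    aligned RNA-seq reads using quality-filtered pileups, dual per-site
    exact tests (binomial error model and Fisher's exact test) with
    Benjamini-Hochberg false discovery rate control, multimapper and SNP
    exclusion, and read-end trimming against random-hexamer mispriming
    artifacts. Classifies calls into the twelve reference-strand mismatch
    types, resolves ADAR (A-to-I) and APOBEC (C-to-U) editing classes by
    gene strand, annotates genomic features, and summarizes and compares
    editomes across conditions. Includes a synthetic-data generator that
    plants editing sites, SNPs, multimapping reads and end-biased
    sequencing errors in a miniature annotated genome with full ground
    truth, plus validation-stage statistics: clone-fraction and
    chromatogram peak-ratio editing frequencies, one-tailed unpaired
    t-tests, 2^-ddCt expression fold changes, and clinical-course summaries
    (mean maximal score, area under the curve, day of onset) for the EAE
    mouse model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
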