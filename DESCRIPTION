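Package: rnabs
Title: RNA Bisulfite Sequencing Analysis for m5C Site Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of RNA bisulfite sequencing (RNA BS-seq)
    data for the identification of 5-methylcytosine (m5C) sites. Implements
    read-level quality filtering and m-bias end trimming, UMI-based PCR
    deduplication with within-group discordance statistics, strand-aware
    methylation calling with spike-in-calibrated bisulfite conversion rate
    estimation, a multi-level high-confidence filter cascade (standard filter,
    Gini-coefficient-guided read C-cutoff, signal/noise ratio, structure-region
    exclusion, binomial testing with Benjamini-Hochberg FDR, replicate
    concordance), transcript annotation with metagene and sequence-context
    profiling, and a seeded bisulfite-read simulator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    BiocGenerics,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
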