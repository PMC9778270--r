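Package: methborder
Title: Two-Phase Differential Methylation Analysis with Promoter-Border
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls differentially methylated regions (DMRs) from CpG-level
    bisulfite or enzymatic methyl-seq count data using a two-phase
    procedure: per-CpG two-group binomial generalized linear model tests
    followed by aggregation of consistent runs of significant sites into
    regions scored with the exact Uniform Product distribution (the
    distribution of a product of independent uniform p-values) and
    Benjamini-Hochberg FDR control across regions.  Also detects
    within-sample low-methylated regions (LMRs), compares pooled regional
    methylation between sample sides with Fisher's exact test, classifies
    DMRs relative to a transcription start site and its unmethylated
    promoter core (promoter-overlapping, upstream border, downstream
    border, or distal), and ships a seeded beta-binomial methylome
    simulator that plants promoter-border DMR/LMR architecture for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
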