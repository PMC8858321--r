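Package: bypassr
Title: Simulation and Analysis of Pooled CRISPR Senescence-Bypass Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide pooled CRISPR/Cas9 positive-selection
    ("bypass") screens against drug-induced proliferative arrest, such as
    CDK4/6-inhibitor-induced senescence. Provides a GeCKOv2-scale sgRNA
    library model with generator and CSV/FASTA I/O, a forward simulator of
    the pooled screen (skewed plasmid representation, infection, 14-day
    selection, multinomial sequencing) with known ground truth, FASTQ
    emission and guide counting with library-coverage QC, reads-per-million
    normalisation and per-sgRNA log2 fold-change enrichment statistics
    (robust-z, non-targeting-control and permutation nulls, per-gene t and
    Wilcoxon summaries), two-criteria gene-level hit calling, hypergeometric
    gene-set overrepresentation of hit lists, and dose-response responder
    classification for multi-cell-line inhibitor panels read out by
    absorbance, including simulation of such panels and secondary-screen
    confirmation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
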