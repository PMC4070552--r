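Package: mitocovbias
Title: Coverage Bias and Sequencing-Error Profiling for Ultra-Deep mtDNA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for per-site coverage bias and sequencing-error
    structure in ultra-deep mitochondrial resequencing data. Parses samtools
    mpileup text into per-site base counts, folds circular-mapping overlaps,
    models coverage as a function of local GC content (linear and quadratic
    regression with AIC comparison, per-base t-tests, site-level ANCOVA),
    scans for sequence-specific-error motifs and their coverage footprint,
    calls candidate heteroplasmic sites from multi-individual pileups,
    estimates per-base error rates from k-mer spectra, and measures
    within-species and cross-species concordance of coverage profiles.
    Includes a synthetic-data generator with known ground truth so every
    stage is testable without access to the original sequencing reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
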