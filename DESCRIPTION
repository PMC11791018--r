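Package: starcall
Title: CYP2D6 Star-Allele Genotyping from Short-Read Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves CYP2D6 star-allele diplotypes from short-read
    sequencing pileups. Provides a versioned star-allele definition
    database with an importer for PharmVar-style downloads, a
    haplotype-insertion read simulator that emits reads with known truth
    alignments, a pileup-based diplotype caller with read-depth copy-number
    estimation against a control gene and tolerance for allelic imbalance,
    a CPIC-style activity-score metabolizer phenotype predictor, and a
    benchmarking module that scores calls against simulated truth with
    alias-aware concordance and function-mismatch accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
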