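Package: sirnadesign
Title: Guideline-Based siRNA Design and RNAi Knockdown Dose-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Design of 21-nt short interfering RNA (siRNA) duplexes for in
    vivo RNA interference in insects, following an eight-criterion guideline:
    core GC content, duplex-end identities, distance from the initiation
    codon, flanking GC content, AU-richness of the antisense seed-proximal
    7-mer, and 3' overhang composition. Candidate target sites are enumerated
    along a transcript, hard-filtered, ranked, and the best non-overlapping
    pair selected. Includes a seeded k-mer off-target scan against a
    transcriptome (complete up to a chosen Hamming distance by pigeonhole word
    sizing), delta-delta-Ct relative expression, an exponential knockdown
    dose-response model with median-effective-concentration estimation, and
    seeded synthetic-data generators for transcripts with planted guideline-
    perfect sites and simulated dose-response experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
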