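Package: dorfscan
Title: Detection and Analysis of Translated Small ORFs in mRNA 3'UTRs from
    Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying translated small open reading frames in
    mRNA untranslated regions from ribosome profiling data, with a focus on
    downstream ORFs (dORFs) in 3'UTRs. Provides candidate ORF enumeration
    (ATG and near-cognate starts), P-site assignment from transcriptomic
    alignments, the signed 3-nucleotide periodicity ORFscore with per-species
    confidence tiers, translation-efficiency comparisons against
    expression-matched resampled control genes, metagene profiling,
    start-codon initiation-context statistics (positional chi-squared, 4-mer
    binomial enrichment, PCA), an ortholog-presence bootstrap, and a fully
    seeded synthetic ribosome-profiling data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
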