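Package: capcnv
Title: Copy-Number and Consequence Analysis for Targeted Sequence Capture in Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coverage-based analysis of targeted sequence-capture data for an
    allotetraploid crop and its two diploid progenitors. Converts per-base
    depth tracks into length-, library- and genome-size-normalized coverage,
    discovers covered regions, classifies copy-number variants between two
    genotypes with a population-reference tiebreak, infers cross-species
    copy status (presence, absence, homoeologous exchange) from
    diploid-on-tetraploid coverage, scans zero-coverage windows for large
    deletions invisible to gapped short-read mapping, filters SNP/InDel
    calls and annotates consequences with Grantham radicality classes,
    builds neighbor-joining trees with bootstrap support, and summarizes
    variation per pathway gene family. Ships a synthetic allopolyploid
    data generator with a machine-readable truth ledger for end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
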