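Package: argsite
Title: Discovery of Side-Chain Arginylation Sites from Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A restricted-database, two-pass MS/MS search pipeline for
    discovering post-translational arginylation on aspartate and glutamate
    side chains: monoisotopic peptidoform mass chemistry, in-silico trypsin/P
    digestion with variable-modification enumeration, a binomial-survival
    spectrum scorer with target-decoy false discovery rate control and
    modification-site localization, scan-exclusion and missed-cleavage
    isobar (terminal arginine) confound filters, protein coverage and depth
    reporting, immunofluorescence band-intensity quantification for retinal
    sections, and exact paired statistics. Ships synthetic-data generators
    (proteomes, spectra, section images) with full ground-truth ledgers so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
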