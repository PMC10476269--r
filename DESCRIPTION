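Package: xlms
Title: Cross-Link Identification from MS2-MS3 Data with MS-Cleavable Cross-Linkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A search pipeline for cross-linking mass spectrometry data acquired
    with MS-cleavable cross-linkers (DSSO, DSBSO) in MS2-MS3 workflows. Detects
    cross-linker-specific doublet peaks in MS2 spectra, maps product MS3 scans to
    their originating doublet peaks, deisotopes and mass-corrects precursors,
    identifies both cross-linked peptides with a binomial fragment-match scorer,
    boosts peptides identified across multiple MSn stages, and validates
    cross-link spectrum matches and cross-links with a two-step target-decoy
    false discovery rate procedure. Includes entrapment filtering, groupwise
    experimentally-validated FDR for synthetic peptide libraries, a synthetic
    benchmark simulator with known ground truth, and exporters to xiNET/xiVIEW.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
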