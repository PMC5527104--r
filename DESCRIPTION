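Package: smpscan
Title: Detection of Significantly Mutated Positions in Domain Family Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps somatic point mutations onto a multiple sequence alignment of
    a homologous protein domain family (such as the human kinome) and scores
    each aligned column with a panel of seven statistical tests against
    empirical null distributions built from mutations falling outside the
    aligned domains. Per-column p-values are combined with Fisher's method and
    aligned positions are called Significantly Mutated Positions (SMPs) by
    Benjamini-Hochberg false discovery rate. Includes a synthetic-data
    generator with planted hotspot columns so the whole pipeline can be
    exercised and calibrated without external data, per-group re-analysis for
    subfamilies of related genes, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
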