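Package: plasmidcomp
Title: Comparative Analysis of Bacterial Megaplasmids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for CDS-level comparative analysis of annotated bacterial
    plasmids. Computes per-CDS best-hit local protein alignment scores and
    relative similarity of a query plasmid against a panel of target plasmids,
    calls putative operons as maximal same-strand gene runs under an
    intergenic-distance threshold, detects iteron-style tandem direct repeats,
    terminal inverted-repeat pairs and target-site duplications, delineates
    Tn3-family transposable elements including truncated and nested
    configurations, chains order-consistent homologues between gene clusters
    (synteny), and runs in-silico PCR. A seeded synthetic-plasmid generator
    plants machine-readable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
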