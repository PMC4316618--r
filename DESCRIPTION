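Package: rasprok
Title: Phylogenomic Census of Prokaryotic Ras-Superfamily Small GTPases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable pipeline for the phylogenomic census of
    small Ras-superfamily GTPases (MglA and Rup families) and their MglB
    (Roadblock/LC7) GTPase-activating partners in prokaryotic genomes. Provides
    iterative homolog harvesting with domain-architecture resolution and
    length-based family delineation, gene-neighborhood coupling and
    stoichiometry analysis, alignment-anchored G1-G5 motif extraction with
    rule-based catalytic-mechanism classification, neighbor-joining bootstrap
    consensus trees, and a coupled-tree coevolution congruence statistic. A
    synthetic-genome generator plants GTPase/MglB systems, decoys and a
    ground-truth manifest so every stage is testable without database
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: mafft (for multiple sequence alignment)
Config/testthat/edition: 3
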