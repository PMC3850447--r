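Package: wgdtrace
Title: Reconstructing Whole Genome Duplications from Gene Family Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers whole genome duplications (WGDs) and triplications (WGTs)
    from the rooted phylogenies of a multi-member gene family. Gene trees are
    reconciled against a rooted species tree by last-common-ancestor mapping;
    duplications are assigned to species-tree branches, per-family copy
    patterns (one-to-two, one-to-two-to-four, triplet) are classified, and
    coordinated duplications across families are called as WGD, WGT, two
    nested WGDs, or single-gene duplications. Includes a deterministic
    ortholog/paralog naming scheme, exon-intron structure congruence scoring
    against a protein alignment, sequence completeness classification, and a
    seeded gene-family evolution simulator with truth tables for validating
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
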