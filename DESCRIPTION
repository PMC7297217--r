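Package: hialign
Title: Hierarchical-Profile Search and Template-Mapped Global Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds very large protein multiple sequence alignments from curated
    hierarchical alignments. A hierarchy of subgroup alignments plus a template
    alignment of node consensus sequences is compiled into position-specific
    scoring profiles; a tree-pruned database search detects domains with
    affine-gap local alignment and Karlin-Altschul statistics, split matches are
    merged, and every hit is projected through the template mapping into the
    root's match columns to give one global alignment. Utilities purge fragments
    and redundant sequences, convert between the mFASTA and cma alignment
    dialects, annotate sequences with phylum/kingdom labels, and score alignment
    quality by the correspondence between top direct-coupling column pairs and
    3D contacts (hypergeometric S-score). A seeded synthetic-superfamily
    simulator with machine-readable ground truth makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
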