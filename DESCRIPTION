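Package: cGLRscreen
Title: Motif Curation, Product Deconvolution and Binding Analysis for
    cGAS-Like Receptor Screens
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational side of kingdom-wide cGAS-like
    receptor (cGLR) discovery and biochemical screening. Implements a
    degenerate active-site motif grammar with variable-length spacers and
    an exhaustive scanner, three-criterion candidate curation with greedy
    centroid redundancy removal, Henderson-Hasselbalch isoelectric-point
    calculation and pI-based ligand-class prediction, cyclic dinucleotide
    enumeration with molecular formula, mass and ESI adduct m/z
    arithmetic, inference of cyclic dinucleotide products from
    radiolabel/phosphatase/nuclease-P1 signatures, single-site binding
    isotherm fitting of EMSA titrations, and gene-family census summaries.
    A seeded synthetic-data module generates proteomes with planted
    motifs, screen observations, binding curves and census tables so
    every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Software, SequenceMatching, Proteomics, MassSpectrometry,
    ImmunoOncology
RoxygenNote: 7.3.3
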