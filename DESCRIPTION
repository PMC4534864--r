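Package: epifidelity
Title: Epigenetic Fidelity of Clonal Plant Propagation via MSAP and
    Methylation-Sensitive GBS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify micropropagation-induced DNA methylation
    change in clonal plants from two complementary assays.  The MSAP track
    turns methylation-sensitive amplified polymorphism peak tables into
    binary and peak-height epilocus matrices, computes PhiPT by
    distance-based AMOVA with permutation tests, principal coordinates
    ordination, and fixed-difference diagnostic markers.  The msGBS track
    demultiplexes methylation-sensitive genotyping-by-sequencing reads by
    exact barcode and MspI cut-site remnant, builds filtered tag-abundance
    matrices, and calls micropropagation-induced differentially methylated
    regions with TMM normalization, quantile-adjusted conditional
    negative-binomial dispersion estimation (common and empirical-Bayes
    tagwise), a two-group exact test, Benjamini-Hochberg FDR control, and a
    cross-variety phase-conserved consensus rule, followed by gene-window
    annotation on a reference genome.  A synthetic-data generator with
    recorded ground truth makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    ape
Config/testthat/edition: 3
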