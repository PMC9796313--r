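Package: tcKinetics
Title: Kinetic Response Classification for Short Treatment Time-Course RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for three-point treatment time courses of bulk
    RNA-seq counts: TMM scaling factors, log-CPM and log2-RPKM transforms,
    mean-variance precision weights feeding weighted per-gene linear models
    with empirical-Bayes moderated t-statistics; an eight-class kinetic
    response taxonomy (immediate, continuous, delayed, transient, each up or
    down) over two sequential contrasts; hypergeometric over-representation
    of ontology terms with graph-distance term clustering and common-parent
    summarization; per-biosynthetic-gene-cluster regulation summaries; and
    rank association of metabolite concentrations with pigment absorbance on
    confrontation-assay agar grids. Includes a negative-binomial simulator
    with planted kinetic classes, toy ontologies and spatial gradient grids
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
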