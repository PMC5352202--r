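Package: somcell
Title: Self-Organizing Map Portrayal of Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps single-cell RNA-seq expression matrices onto a
    self-organizing map (SOM) of metagenes so that every cell becomes a
    two-dimensional expression "portrait". On top of the portraits the
    package segments over-expression spot modules, discovers cell groups
    from pairwise portrait correlations with silhouette-guided model
    selection, scores gene sets by Fisher's exact test and a
    variance-shrunken gene set Z-score (GSZ), and infers large-scale copy
    number variation from chromosome-ordered windowed expression
    averages. A fully parameterised synthetic-data generator with planted
    expression programs, rare subpopulations, dropout and copy-number
    events provides ground truth for every stage, so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    zoo
Suggests:
    EBImage,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
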