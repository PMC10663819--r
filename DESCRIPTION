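Package: CCCscreen
Title: Screening Cell-Cell Communication Channels Specific to a Focal
    Cell Population in Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers ligand-receptor communication between annotated
    single-cell clusters and screens for channels used specifically by a
    focal (e.g. malignant) population. Implements family-level
    communication-gene expression scores with cross-cluster z-scores and
    tumor versus adjacent-tissue contrasts; cluster-pair communication
    scores summed over a curated ligand-receptor database with
    heterodimeric complexes; per-interaction emitter- and receiver-summed
    scores with a fold-ratio specificity rule and a Wilcoxon differential
    expression gate; cross-dataset intersection of hits; and a bulk
    RNA-seq validation based on per-sample ligand-by-receptor expression
    products. Ships a negative-binomial single-cell and bulk simulator
    with planted communication channels so the full screen is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    DESeq2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, GeneExpression, Software
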