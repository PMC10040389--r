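Package: mcdmTools
Title: Multicellular Disease Models and Connective Pathway Analysis for
    Multi-Organ Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organizes differential-expression results from many organs and
    cell types into multicellular disease models (MCDMs): directed multigraphs
    in which cell types are nodes and predicted upstream regulators (URs) are
    edges carrying their downstream target genes. Builds multi-organ MCDMs
    restricted to extracellular (blood-transportable) URs, ranks URs by
    downstream reach, clusters enriched pathways into programs and subprograms
    by 1-Jaccard distance of their DEG-restricted gene sets, labels pathway
    activation per group, links URs to programs with Fisher's-method
    meta-combination, screens backup ("takeover") URs in treatment
    non-responders, and annotates single cells by reference matching with
    monotonic-regression projection and purity-escalated Leiden clustering.
    A synthetic-data module generates every input with known ground truth so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'enrichment.R'
    'celltyping.R'
    'connective.R'
    'interactions.R'
    'io.R'
    'mcdmTools-package.R'
    'ur_programs.R'
    'synthetic.R'
    'pipeline.R'
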