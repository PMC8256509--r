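Package: osteoMetNet
Title: Integrated Biomarker and Metabolite Prioritization for
    Osteosarcoma Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated re-analysis toolkit for two-group osteosarcoma
    expression studies: empirical-Bayes moderated differential expression,
    hypergeometric over-representation analysis, sample-wise gene-set
    variation scoring, confidence-filtered protein-protein interaction
    networks with disease-table intersection, median-split Kaplan-Meier
    prognostic screening, and a heat-diffusion model on heterogeneous
    KEGG-style metabolic graphs that prioritizes disease-associated
    metabolites and assembles a disease-metabolic network. Includes a
    synthetic-data module with planted ground truth so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
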