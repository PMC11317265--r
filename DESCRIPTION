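Package: tlsQuant
Title: Quantification and Prognostic Analysis of Tertiary Lymphoid Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying tertiary lymphoid structures (TLSs) in solid
    tumours, with defaults tuned for gastric adenocarcinoma. Implements
    single-sample gene-set enrichment (ssGSEA) scoring of TLS, germinal-centre
    and dendritic-cell signatures with survival-based dichotomization;
    spatial partitioning of tumour sections into tumour centre and invasive
    margin (a 2.5 mm band on each side of the tumour boundary) with the six
    count/density TLS scores; Kaplan-Meier, log-rank, maximally selected
    rank-statistic cutpoints and Cox proportional-hazards modelling;
    clinicopathological association tests; and multiplex-immunofluorescence
    cell-composition analytics (phenotyping, per-compartment percentages,
    co-expression fractions, co-infiltration clustering). A synthetic-data
    generator produces expression cohorts, tissue geometries with TLS events
    and per-cell marker tables with the statistical structure the analysis
    assumes, so the full pipeline is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
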