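Package: oncodisco
Title: Staged In-Silico Small-Molecule Screening for Oncology Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-stage, fully seeded drug-discovery pipeline for oncology:
    prognostic target identification from expression and survival endpoints
    (median-split outcome classification with tabular augmentation and
    Lasso feature ranking), tumor/normal discriminative filtering,
    literature co-occurrence mining, drug-protein interaction prediction on
    summed k-mer and circular-substructure embeddings with lower-quartile
    negative sampling, and preclinical IC50-success emulation with a
    selectivity filter over cell-line panels. Ships a synthetic-data module
    that plants recoverable signal in every input so each stage has a
    parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    Matrix,
    MASS,
    methods,
    nnet,
    glmnet,
    igraph,
    ChemmineR,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
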