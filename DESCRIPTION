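Package: phenodx
Title: Phenotype-Driven Rare-Disease Differential Diagnosis
Version: 0.1.0
Authors@R:
    person("phenodx", "maintainers", email = "maintainers@phenodx.dev",
           role = c("aut", "cre"))
Description: Ranks candidate rare diseases from a patient's phenotype terms
    using an ontology of phenotypic abnormalities. Implements information
    content and most-informative-common-ancestor (MICA) semantic similarity,
    TF-IDF-Hierarchy term weighting, two similarity-based ranking models
    (phenotype-vector and gene-vector), two machine-learning ensemble models
    over synthetic training patients, a Bayesian-averaging score combiner,
    top-k diagnostic evaluation (precision/recall/F1, confusion matrix,
    ranking distribution, query-size sensitivity), a synthetic-data generator
    for ontologies, disease knowledge bases, gene maps and patient cohorts,
    and a command-line interface for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    FNN,
    jsonlite,
    digest,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
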