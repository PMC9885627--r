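Package: gwasnet
Title: Case-Control SNP Prioritization with Residue-Network Co-Mutation Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for prioritizing coding-region SNPs from
    case-control genotype data: an eight-step genotype quality-control cascade
    (polymorphism, sex concordance, autosome restriction, call rates, minor
    allele frequency, ancestry outliers, Hardy-Weinberg exact filtering),
    per-variant association under additive, dominant and recessive codings
    with Cochran-Armitage trend tests and Wald odds-ratio intervals, a
    training/validation/combined association workflow, multivariable
    genotype-plus-lifestyle logistic risk models with ROC/AUC diagnostics,
    and structure-based co-mutation prioritization: a residue-contact network
    is built from protein coordinates and catalogued mutation sites closer to
    a focal mutated residue than its mean network distance are selected as
    co-mutation candidates and ranked by tabulated protein-stability changes
    (ddG). A synthetic-data module generates genotype matrices, covariate
    tables and toy structures with known properties so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
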