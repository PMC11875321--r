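Package: myoCytokines
Title: Cytokine and Immune-Checkpoint Expression Patterns in Myositis Muscle Biopsies
Version: 0.1.0
Authors@R:
    person("Muscle", "Transcriptomics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cytokine, cytokine-receptor and
    immune-checkpoint expression in bulk RNA-seq of muscle biopsies from
    myositis patients. Implements trimmed-mean-of-M-values (TMM)
    normalization, empirical-Bayes moderated-t differential expression with
    dual one-vs-rest and versus-normal-tissue contrasts, hierarchy-aware
    group-specificity classification of differentially expressed gene sets
    (clinical groups and autoantibody subgroups), exclusive Venn-region set
    algebra, marker-correlation matrices, and type-1/2/3 inflammation
    signature summaries. Includes a negative-binomial synthetic-data
    generator with planted group effects and latent immune-infiltration and
    muscle-regeneration factors so the whole pipeline is testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
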