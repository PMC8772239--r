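Package: steGO
Title: Gene Functional Similarity from the Specificity of Terms and Edges in
    the Gene Ontology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes gene functional similarity over the Gene Ontology with
    the STE (specificity of terms and edges) model: a structural information
    content (IC) for every term from its depth, ancestor depths and descendant
    count; a specificity weight for every is_a/part_of edge from descendant IC
    mass; a decomposition of each term's IC into an inherited part propagated
    from its parents and an own part specific to the term; the IC of an
    ancestor-closed term set as the sum of own-IC values; and gene-gene
    similarity as the ratio of intersection to union set-IC. Ships the
    corpus-based and Sanchez structural IC baselines, the Resnik (best-match
    average), simUI, vector-space cosine and simGIC gene similarity baselines,
    OBO and GAF 2.x readers with evidence-code stratification, a synthetic
    ontology/annotation generator, and evaluation harnesses (ROC/AUC on
    labeled interaction pairs, Pearson correlation against expression
    similarity, within/between functional-class summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
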