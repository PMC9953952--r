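Package: kgxplain
Title: Explainable Variant Pathogenicity Classification over Annotation Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds an integrated annotation knowledge graph from simplified
    ClinVar-, COSMIC-, dbNSFP- and dbscSNV-style tables with per-gene and
    per-variant hub nodes, classifies missense variants as pathogenic or
    benign from per-variant feature subgraphs, and generates ranked
    natural-language explanation sentences from declarative rules weighted
    by perturbation-based edge attribution. Includes decision-tree and
    random-forest baselines over flattened feature vectors, a
    chromosome-disjoint five-fold cross-validation harness, and a synthetic
    data generator with a planted, tunable pathogenicity signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    ranger,
    rpart,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
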