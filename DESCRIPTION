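Package: mutrelex
Title: Mutation-Gene and Mutation-Drug Relation Extraction from Annotated
    Biomedical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts mutation-gene and mutation-drug relations from
    entity-annotated biomedical text at the document and sentence level.
    Provides a PubTator-format corpus reader, HGVS-style protein mutation
    normalization, a wild-type residue sequence filter, a local entity
    co-occurrence search index yielding four search-score features,
    distance/frequency document features, distant-supervision sentence
    dataset construction, feature-based classifiers (decision tree, random
    forest), a convolutional sentence classifier with word, entity-type and
    position embeddings fused with scalar score features, skip-gram word
    vector training, evaluation protocols (balanced cross-validation,
    repeated random sub-sampling), a co-occurrence baseline, relation table
    export and gold-list comparison, and a seeded synthetic corpus
    generator for end-to-end exercise of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
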