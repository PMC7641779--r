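Package: pgxkit
Title: Pharmacogenomics Knowledge Model Toolkit for Drug Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates a typed pharmacogenomics knowledge model from
    drug-label text. Provides the entity/relation schema with structural
    validation, a drug-label annotation corpus layer (character-offset spans,
    BIO conversion, inter-annotator agreement), a feature-based linear-chain
    conditional random field tagger with exact inference and entity-level
    evaluation, normalization of relation surface expressions to registry
    relations, a validated triple store with risk-factor queries and export,
    parsers for structured product label, DrugBank and RxNorm source dialects,
    and a seeded synthetic drug-label generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
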