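Package: conceptvec
Title: Biomedical Concept Embeddings from Annotated Literature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds concept-normalized training corpora from PubTator-annotated
    abstracts, trains concept embeddings with four methods (continuous bag-of-words
    and skip-gram with negative sampling, GloVe co-occurrence factorization, and a
    fastText variant whose character n-gram representation is disabled for
    normalized bio-concept tokens), and evaluates the embeddings intrinsically
    (group-level similarity difference between related and unrelated concept sets)
    and extrinsically (protein-protein interaction pair prediction and five-class
    drug-drug interaction sentence classification). Includes seeded synthetic-data
    generators with planted cluster structure for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
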