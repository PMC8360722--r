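Package: cddf
Title: Core Drug Discovery from Medical Literature via Subword Embeddings
    and Overlapping Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A literature-based drug discovery toolkit for traditional
    Chinese medicine corpora. Cleans and segments Chinese-language medical
    text, trains a subword word-embedding model whose features are
    sliding-window substrings of per-character stroke, structure and pinyin
    codes (with a whole-word continuous skip-gram baseline), builds a drug
    similarity network from cosine similarity of the learned context
    vectors, detects overlapping drug communities by label propagation with
    belonging coefficients (COPRA), and ranks core drugs by network degree.
    Includes network analytics (degree, component-scaled closeness
    centrality, size distributions) and a synthetic corpus generator with
    planted drug-community structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
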