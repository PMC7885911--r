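Package: topicsift
Title: Iterative Topic-Model Relevance Filtering for Noisy Text Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts clinically relevant documents and granular clinical
    topics from large, noisy short-text corpora (such as social-media posts)
    without manual labeling. The method alternates Latent Dirichlet
    Allocation topic modeling with clinical-concept-based relevance scoring:
    documents by self-identified healthcare professionals seed the filter,
    concept trigger words are scored by their per-document rate in kept
    versus discarded documents, topics are ranked by the relevance of the
    concepts in their associated documents, and documents weakly associated
    with relevant topics are dropped. Iterating the loop progressively
    enriches the corpus for clinical content. Includes a dictionary concept
    annotator, a reader for precomputed fielded concept annotations, UMass
    topic coherence and concept-fraction topic diagnostics, n-gram enrichment
    tables, time-windowed micro-trend detection, and a synthetic corpus
    generator with planted ground truth for evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lubridate,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
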