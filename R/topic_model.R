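#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Fits a k-topic Latent Dirichlet Allocation model over tokenized
#' documents and returns the document-topic matrix theta (k x M; the entry
#' for topic t and document m estimates the probability that a word of m
#' was sampled from t) and the topic-word matrix beta (k x V). Both are
#' taken from the final sampler state, smoothed by the priors, so theta
#' columns and beta rows each sum to 1. Documents with zero tokens are
#' excluded from sampling, flagged, and given uniform theta columns.
#'
#' @param tokdocs Named list of token vectors (see [tokenize_corpus()]).
#' @param k Number of topics (>= 2). The pipeline default is 100, which
#'   balances topic granularity against summarizability on corpora of
#'   10^5-10^6 short documents; small evaluation corpora use 10-50.
#' @param seed Integer seed for the sampler's private RNG; fixed seed and
#'   corpus give identical fits regardless of R's RNG state.
#' @param alpha Symmetric document-topic prior (default `5 / k`).
#' @param eta Symmetric topic-word prior (default 0.01).
#' @param iterations Gibbs sweeps (default 1000).
#' @return A `sift_lda` object: list with `k`, `vocabulary`, `theta`
#'   (columns named by doc_id), `beta` (columns named by term),
#'   `doc_ids`, `empty_docs` (ids of zero-token documents), and the
#'   hyperparameters used.
#' @export
fit_lda <- function(tokdocs, k, seed = 13, alpha = 5 / k, eta = 0.01,
                    iterations = 1000) {
  stopifnot(k >= 2, iterations >= 1)
  lens <- lengths(tokdocs)
  if (length(tokdocs) == 0 || all(lens == 0)) {
    stop("nothing to model: corpus is empty after dropping zero-token documents",
         call. = FALSE)
  }
  empty_ids <- names(tokdocs)[lens == 0]
  kept <- tokdocs[lens > 0]
  vocab <- sort(unique(unlist(kept, use.names = FALSE)))
  ids <- lapply(kept, function(t) match(t, vocab) - 1L)
  fit <- lda_gibbs_cpp(ids, as.integer(k), length(vocab),
                       alpha, eta, as.integer(iterations),
                       as.integer(seed))
  theta <- matrix(1 / k, nrow = k, ncol = length(tokdocs),
                  dimnames = list(NULL, names(tokdocs)))
  theta[, names(kept)] <- fit$theta
  beta <- fit$beta
  colnames(beta) <- vocab
  structure(
    list(k = k, vocabulary = vocab, theta = theta, beta = beta,
         doc_ids = names(tokdocs), empty_docs = empty_ids,
         alpha = alpha, eta = eta, iterations = iterations, seed = seed),
    class = "sift_lda"
  )
}

#' @export
print.sift_lda <- function(x, ...) {
  cat(sprintf("<sift_lda: %d topics, %d documents, vocabulary %d>\n",
              x$k, ncol(x$theta), length(x$vocabulary)))
  invisible(x)
}

#' Highest-weight words of a topic
#'
#' @param model A `sift_lda`.
#' @param topic Topic index in 1..k.
#' @param n Number of words (default 10). Ties in beta are broken by
#'   vocabulary order, so the listing is deterministic.
#' @return Character vector of up to `n` terms, by descending beta.
#' @export
top_words <- function(model, topic, n = 10) {
  stopifnot(topic >= 1, topic <= model$k)
  ord <- order(-model$beta[topic, ], model$vocabulary)
  model$vocabulary[ord][seq_len(min(n, length(ord)))]
}

#' Fraction of top topic words that are clinical concepts
#'
#' For each topic, the fraction of its `n` highest-beta words that are found
#' in the concept lexicon. A word counts as found if it equals a
#' single-token lexicon phrase or appears as a token of a multiword phrase.
#' This approximates how clinically interesting the model is as a whole.
#'
#' @param model A `sift_lda`.
#' @param lexicon A `sift_lexicon`.
#' @param n Top-word count per topic (default 10).
#' @return List with `per_topic` (numeric vector, one per topic) and
#'   `mean` (unweighted mean over topics).
#' @export
concept_fraction <- function(model, lexicon, n = 10) {
  lex_words <- unique(unlist(strsplit(lexicon$phrase, " ", fixed = TRUE)))
  per <- vapply(seq_len(model$k), function(t) {
    tw <- top_words(model, t, n)
    sum(tw %in% lex_words) / n
  }, numeric(1))
  list(per_topic = per, mean = mean(per))
}

#' UMass coherence of fitted topics
#'
#' For each topic's top-n word list `w_1..w_n` (descending beta), the score
#' is `sum_{i=2..n} sum_{j<i} log((D(w_i, w_j) + 1) / D(w_j))`, where
#' `D(w)` is the number of documents containing `w` and `D(w, w')` the
#' number containing both. Higher (less negative) is more coherent. Words
#' absent from the corpus contribute through the +1 smoothing; a reference
#' word with zero document frequency uses `eps_df` in the denominator.
#'
#' @param model A `sift_lda`.
#' @param tokdocs Tokenized corpus providing document-frequency counts.
#' @param n Top-word count per topic (default 10).
#' @param eps_df Denominator substitute for zero-df reference words
#'   (default 1 document).
#' @return List with `per_topic` and `mean`.
#' @export
umass_coherence <- function(model, tokdocs, n = 10, eps_df = 1) {
  doc_sets <- lapply(tokdocs, unique)
  per <- vapply(seq_len(model$k), function(t) {
    tw <- top_words(model, t, n)
    in_doc <- vapply(doc_sets, function(s) tw %in% s,
                     logical(length(tw)))
    if (length(tw) == 1) in_doc <- matrix(in_doc, nrow = 1)
    df <- rowSums(in_doc)
    score <- 0
    for (i in seq_along(tw)[-1]) {
      for (j in seq_len(i - 1)) {
        co <- sum(in_doc[i, ] & in_doc[j, ])
        denom <- if (df[j] > 0) df[j] else eps_df
        score <- score + log((co + 1) / denom)
      }
    }
    score
  }, numeric(1))
  list(per_topic = per, mean = mean(per))
}

#' Dump a fitted model to TSV files
#'
#' Writes `theta.tsv` (topics x documents with a doc_id header) and
#' `top_words.tsv` (topic_id, rank, word, weight) under `dir`.
#'
#' @param model A `sift_lda`.
#' @param dir Output directory (created if needed).
#' @param n_words Words per topic in the listing (default 10).
#' @return `dir`, invisibly.
#' @export
write_lda <- function(model, dir, n_words = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  theta_df <- as.data.frame(model$theta)
  utils::write.table(theta_df, file.path(dir, "theta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rows <- do.call(rbind, lapply(seq_len(model$k), function(t) {
    tw <- top_words(model, t, n_words)
    data.frame(topic_id = t, rank = seq_along(tw), word = tw,
               weight = model$beta[t, tw], stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file.path(dir, "top_words.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
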