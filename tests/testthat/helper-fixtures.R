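# Small corpora and lexicons built in code for the unit tests.

make_corpus <- function(n = 5, seed = NULL, thread_id = NA_character_) {
  texts <- paste("alpha beta word", seq_len(n))
  corpus(
    doc_id = sprintf("d%02d", seq_len(n)),
    text = texts,
    author_name = sprintf("Author %d", seq_len(n)),
    author_handle = sprintf("handle%d", seq_len(n)),
    author_bio = "just a person",
    created_at = as.POSIXct("2020-03-01 12:00:00", tz = "UTC") +
      3600 * seq_len(n),
    thread_id = thread_id
  )
}

random_corpus <- function(n, seed) {
  set.seed(seed)
  words <- c("fever", "cough", "mask", "dog", "game", "lung", "rain",
             "vote", "icu", "trial", "café", "été")
  texts <- vapply(seq_len(n), function(i) {
    paste(sample(words, sample(3:8, 1), replace = TRUE), collapse = " ")
  }, character(1))
  corpus(
    doc_id = sprintf("r%03d", seq_len(n)),
    text = texts,
    author_name = sample(c("Ann MD", "Bob", "Cara RN", "Dee"), n,
                         replace = TRUE),
    author_handle = sprintf("user%03d", seq_len(n)),
    author_bio = sample(c("physician at hospital", "loves hiking",
                          "public health nerd", ""), n, replace = TRUE),
    created_at = as.POSIXct("2020-03-01", tz = "UTC") +
      sample.int(86400 * 30, n),
    thread_id = ifelse(stats::runif(n) < 0.3, "t1", NA_character_)
  )
}

tiny_lexicon <- function() {
  concept_lexicon(
    phrase = c("fever", "cough", "lung", "icu", "trial",
               "pulmonary embolism", "embolism"),
    cui = sprintf("C%07d", 1:7),
    preferred_name = c("Fever", "Cough", "Lung", "ICU", "Trial",
                       "Pulmonary embolism", "Embolism"),
    semantic_types = "T047"
  )
}

# token lists keyed by doc id, handy for relevance/coherence oracles
toy_tokdocs <- function(n_docs, vocab, seed, min_len = 2, max_len = 10) {
  set.seed(seed)
  out <- lapply(seq_len(n_docs), function(i) {
    sample(vocab, sample(min_len:max_len, 1), replace = TRUE)
  })
  names(out) <- sprintf("t%03d", seq_len(n_docs))
  out
}

# independent brute-force recomputation of the term relevance ratio,
# written directly from the definition; used as the oracle
brute_relevance <- function(term, kept, ref, eps = 0.001) {
  fA <- sum(unlist(kept) == term)
  fB <- sum(unlist(ref) == term)
  (fA / length(kept) + eps) / ((fB - fA) / (length(ref) - length(kept)) + eps)
}
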