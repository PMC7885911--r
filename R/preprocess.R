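#' Default query-term list
#'
#' Terms used to collect the corpus (dataset keywords); removed from every
#' tokenized document because they appear in essentially all posts and carry
#' no discriminative signal.
#'
#' @return Character vector.
#' @export
default_query_terms <- function() {
  c("covid", "covid19", "coronavirus", "2019ncov", "sarscov2")
}

#' Default English stopword list
#'
#' The Snowball English stopword list shipped with the package (plain text,
#' one term per line) so tokenization is reproducible.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "topicsift")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

#' Read a term list file (stopwords, query terms)
#'
#' @param path One term per line; `#` comment lines and blanks ignored.
#' @return Character vector.
#' @export
read_term_list <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

# Contraction table, applied case-insensitively before lowercasing.
# "can't" -> "can not" so both pieces hit the stopword list.
contractions <- c(
  "can't" = "can not", "won't" = "will not", "shan't" = "shall not",
  "n't" = " not", "'ll" = " will", "'re" = " are", "'ve" = " have",
  "'m" = " am", "'d" = " would", "let's" = "let us", "'s" = ""
)

expand_contractions <- function(text) {
  text <- gsub("’", "'", text)
  for (i in seq_along(contractions)) {
    text <- gsub(names(contractions)[i], contractions[[i]], text,
                 ignore.case = TRUE, fixed = FALSE)
  }
  text
}

# Emoji and pictograph removal by Unicode block.
strip_emoji <- function(text) {
  cls <- paste0("[\u2190-\u21ff\u2600-\u27bf\u2b00-\u2bff",
                "\ufe0f\u200d\U0001F000-\U0001FAFF]")
  gsub(cls, "", text, perl = TRUE)
}

irregular_lemmas <- c(
  children = "child", feet = "foot", teeth = "tooth", mice = "mouse",
  men = "man", women = "woman", people = "people", data = "data",
  viruses = "virus", diagnoses = "diagnosis", analyses = "analysis",
  crises = "crisis", sequelae = "sequela", criteria = "criterion",
  phenomena = "phenomenon", went = "go", gone = "go", said = "say",
  made = "make", done = "do", seen = "see", taken = "take",
  given = "give", found = "find", died = "die", dying = "die",
  lives = "life", better = "good", worse = "bad", left = "leave",
  felt = "feel", lying = "lie", being = "be", has = "have", had = "have",
  was = "be", were = "be", is = "be", are = "be"
)

vowels <- c("a", "e", "i", "o", "u")

# Rule + exception-dictionary English lemmatizer. Contract: plural nouns ->
# singular, inflected verbs -> base form, noun reading preferred when the
# part of speech is ambiguous; unknown words pass through unchanged. It is
# idempotent on its own output, which the tokenizer relies on.
lemmatize_token <- function(tok) {
  hit <- irregular_lemmas[tok]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(tok)
  if (n > 4 && endsWith(tok, "ies")) {
    return(paste0(substr(tok, 1, n - 3), "y"))
  }
  if (n > 4 && (endsWith(tok, "sses") || endsWith(tok, "xes") ||
                endsWith(tok, "ches") || endsWith(tok, "shes") ||
                endsWith(tok, "zes"))) {
    return(substr(tok, 1, n - 2))
  }
  if (n > 3 && endsWith(tok, "s") &&
      !endsWith(tok, "ss") && !endsWith(tok, "us") && !endsWith(tok, "is")) {
    return(substr(tok, 1, n - 1))
  }
  if (n >= 6 && endsWith(tok, "ing")) {
    stem <- substr(tok, 1, n - 3)
    return(undouble(stem))
  }
  if (n >= 5 && endsWith(tok, "ed")) {
    stem <- substr(tok, 1, n - 2)
    return(undouble(stem))
  }
  tok
}

# running -> run; stopped -> stop; ll/ss endings kept (falling -> fall)
undouble <- function(stem) {
  n <- nchar(stem)
  if (n >= 3) {
    last <- substr(stem, n, n)
    prev <- substr(stem, n - 1, n - 1)
    if (last == prev && !last %in% c("l", "s") && !last %in% vowels) {
      return(substr(stem, 1, n - 1))
    }
  }
  stem
}

lemmatize <- function(tokens) {
  vapply(tokens, lemmatize_token, character(1), USE.NAMES = FALSE)
}

#' Normalize raw post text into tokens
#'
#' Applies, in order: strip HTML tags; remove URLs and @-mentions; expand
#' contractions; remove emoji; lowercase; split "#tag" to "tag"; tokenize
#' on non-alphanumeric characters; lemmatize; drop stopwords, query terms,
#' and 1-character tokens. The output token list may be empty (e.g. a post
#' consisting only of a URL).
#'
#' @param text Character vector of raw texts.
#' @param query_terms Terms to drop (see [default_query_terms()]).
#' @param stopwords Stopword list (see [default_stopwords()]).
#' @return A list of character vectors, one per input text.
#' @export
normalize_text <- function(text, query_terms = default_query_terms(),
                           stopwords = default_stopwords()) {
  text <- enc2utf8(as.character(text))
  text <- gsub("<[^>]+>", " ", text)               # HTML tags
  text <- gsub("https?://\\S+|www\\.\\S+", " ", text)  # URLs
  text <- gsub("(^|\\s)@[A-Za-z0-9_]+", " ", text)     # @-mentions
  text <- expand_contractions(text)
  text <- strip_emoji(text)
  text <- tolower(text)
  text <- gsub("#([a-z0-9])", "\\1", text)         # "#tag" -> "tag"
  drop <- unique(c(tolower(stopwords), tolower(query_terms)))
  lapply(strsplit(text, "[^a-z0-9]+"), function(toks) {
    toks <- toks[nzchar(toks)]
    toks <- lemmatize(toks)
    toks[nchar(toks) > 1 & !toks %in% drop]
  })
}

#' Tokenize every document of a corpus
#'
#' @param x A `sift_corpus`.
#' @inheritParams normalize_text
#' @return A named list of token vectors keyed by `doc_id`, carrying the
#'   corpus label as attribute `"label"`.
#' @export
tokenize_corpus <- function(x, query_terms = default_query_terms(),
                            stopwords = default_stopwords()) {
  toks <- normalize_text(x$text, query_terms, stopwords)
  names(toks) <- x$doc_id
  attr(toks, "label") <- corpus_label(x)
  toks
}

#' Contiguous n-grams of a token sequence
#'
#' Returns every contiguous n-gram for n = 1..`max_n` joined by single
#' spaces, with multiset semantics (repeated n-grams appear repeatedly). A
#' token sequence of length L yields L + (L-1) + ... + (L-max_n+1) n-grams.
#'
#' @param tokens Character vector of tokens.
#' @param max_n Largest n-gram order (default 3).
#' @return Character vector of n-grams.
#' @export
extract_ngrams <- function(tokens, max_n = 3) {
  stopifnot(max_n >= 1)
  L <- length(tokens)
  out <- list()
  for (n in seq_len(max_n)) {
    if (L < n) break
    if (n == 1) {
      out[[n]] <- tokens
    } else {
      idx <- seq_len(L - n + 1)
      mat <- vapply(seq_len(n) - 1L,
                    function(off) tokens[idx + off], character(length(idx)))
      if (length(idx) == 1) mat <- matrix(mat, nrow = 1)
      out[[n]] <- apply(mat, 1, paste, collapse = " ")
    }
  }
  unlist(out) %||% character(0)
}
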