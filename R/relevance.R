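#' Term relevance between a kept corpus and its reference
#'
#' The scoring core of the iterative filter. For a kept corpus A contained
#' in a reference corpus B, the relevance of a term c is
#'
#'   Rel(c; A, B) = (f_A(c) / |A| + eps) / ((f_B(c) - f_A(c)) / (|B| - |A|) + eps)
#'
#' where `f_A`, `f_B` count *occurrences* of c (so a term can occur more
#' often than there are documents), `|A|`, `|B|` count documents, and `eps`
#' is a small constant preventing division by zero. The score compares the
#' term's per-document rate among kept documents with its rate among
#' discarded documents (B minus A): equal rates give exactly 1, a term seen
#' only in A scores far above 1, and a term never seen in either corpus
#' scores eps/eps = 1.
#'
#' @param term Character vector of terms (returned as names).
#' @param f_A,f_B Occurrence counts of each term in A and B (recycled);
#'   must satisfy `f_B >= f_A >= 0`.
#' @param size_A,size_B Document counts |A| and |B|, with
#'   `size_B > size_A > 0`.
#' @param eps Smoothing constant, default 0.001.
#' @return Named numeric vector of non-negative scores.
#' @export
term_relevance <- function(term, f_A, f_B, size_A, size_B, eps = 0.001) {
  if (eps <= 0) stop("eps must be positive", call. = FALSE)
  if (size_B <= size_A || size_A <= 0) {
    stop("need |B| > |A| > 0 (reference set B \\ A must be non-empty)",
         call. = FALSE)
  }
  n <- length(term)
  f_A <- rep_len(as.numeric(f_A), n)
  f_B <- rep_len(as.numeric(f_B), n)
  if (any(f_A < 0) || any(f_B < 0)) {
    stop("negative occurrence counts", call. = FALSE)
  }
  if (any(f_B < f_A)) {
    stop("f_B must be >= f_A for every term (A is contained in B)",
         call. = FALSE)
  }
  out <- (f_A / size_A + eps) / ((f_B - f_A) / (size_B - size_A) + eps)
  names(out) <- term
  out
}

count_terms <- function(term_lists) {
  tab <- table(unlist(term_lists, use.names = FALSE))
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

new_relevance_table <- function(scores, kept_label, ref_label, eps) {
  structure(
    tibble::tibble(term = names(scores), score = unname(scores)),
    class = c("sift_relevance", class(tibble::tibble())),
    kept_label = kept_label, ref_label = ref_label, eps = eps
  )
}

#' Relevance table under the iteration reference schedule
#'
#' Builds the term -> relevance table used at filtering iteration `i`. The
#' reference pair follows a fixed schedule: at i = 1 the kept corpus is D1
#' (HCP-authored) scored against the raw corpus D0; at i > 1 the current
#' corpus Di is scored against D1, which stays the fixed baseline. Holding
#' D1 fixed stabilizes the scores across iterations and avoids collapsing
#' onto a single topic.
#'
#' @param i Iteration index (>= 1).
#' @param term_lists_by_corpus Named list with elements `D0`, `D1`, and
#'   (for i > 1) `Di`: each a list, per document, of the scoring units —
#'   concept trigger strings, all tokens (for the all-words variant), or
#'   n-grams (for enrichment reports).
#' @param labels Optional c(kept, ref) labels; defaults to the schedule's.
#' @param eps Smoothing constant.
#' @return A `sift_relevance` tibble (`term`, `score`) with attributes
#'   `kept_label`, `ref_label`, `eps`; terms sorted by descending score.
#' @export
relevance_schedule <- function(i, term_lists_by_corpus, labels = NULL,
                               eps = 0.001) {
  stopifnot(i >= 1)
  pick <- function(name) {
    x <- term_lists_by_corpus[[name]]
    if (is.null(x)) {
      stop("relevance schedule at i=", i, " needs corpus '", name, "'",
           call. = FALSE)
    }
    x
  }
  if (i == 1) {
    kept <- pick("D1"); ref <- pick("D0")
    if (is.null(labels)) labels <- c("D1", "D0")
  } else {
    kept <- pick("Di"); ref <- pick("D1")
    if (is.null(labels)) labels <- c(paste0("D", i), "D1")
  }
  fA <- count_terms(kept)
  fB <- count_terms(ref)
  terms <- union(names(fA), names(fB))
  fa <- ifelse(terms %in% names(fA), fA[terms], 0)
  fb <- ifelse(terms %in% names(fB), fB[terms], 0)
  scores <- term_relevance(terms, fa, fb, length(kept), length(ref),
                           eps = eps)
  scores <- sort(scores, decreasing = TRUE)
  new_relevance_table(scores, labels[1], labels[2], eps)
}

#' Score topics by the relevance of their documents' concepts
#'
#' The score of topic t is the theta-weighted mean, over documents m, of
#' the document's total concept relevance:
#'
#'   Score(t) = sum_m theta[t, m] * RelSum(m) / sum_m theta[t, m]
#'
#' where `RelSum(m)` sums the relevance of every concept mention in m
#' (per occurrence). Documents with no mentions contribute 0; triggers
#' absent from the relevance table (e.g. removed by the concept pre-filter)
#' contribute 0. Topics whose documents are dominated by highly relevant
#' concepts therefore score highest. Note the topic's own word list plays
#' no role here, so relevant words unknown to the concept lexicon can still
#' weigh heavily in a high-scoring topic.
#'
#' @param model A `sift_lda`.
#' @param term_lists Per-document scoring units, named by doc_id: concept
#'   triggers from [annotate()] (use [mentions_by_doc()]) or token lists
#'   for the all-words variant.
#' @param rel A `sift_relevance` table.
#' @return Named numeric vector of topic scores (length k).
#' @export
score_topics <- function(model, term_lists, rel) {
  theta <- model$theta
  mass <- rowSums(theta)
  if (any(mass <= 0)) {
    stop("topic with zero total theta mass cannot be normalized",
         call. = FALSE)
  }
  lookup <- rel$score
  names(lookup) <- rel$term
  relsum <- vapply(colnames(theta), function(d) {
    terms <- term_lists[[d]]
    if (is.null(terms) || length(terms) == 0) return(0)
    s <- lookup[terms]
    sum(s, na.rm = TRUE)
  }, numeric(1))
  as.vector(theta %*% relsum) / mass
}

#' Group mention triggers by document
#'
#' @param mentions Mentions tibble from [annotate()].
#' @param doc_ids All document ids of the corpus (documents without
#'   mentions get empty entries).
#' @return Named list of trigger character vectors.
#' @export
mentions_by_doc <- function(mentions, doc_ids) {
  out <- split(mentions$trigger, factor(mentions$doc_id, levels = doc_ids))
  lapply(out, as.character)
}

#' Select relevant topics by thresholding scores
#'
#' Retains the topics whose score clears a fraction tau of the way from
#' the minimum topic score to the maximum:
#'
#'   R = { t : Score(t) >= (S_max - S_min) * tau + S_min }
#'
#' with `>=` at the cutoff. tau = 0 keeps every topic, tau = 1 keeps only
#' the argmax set; the default 0.25 keeps a diverse set of
#' clinically-relevant topics while discarding the bulk. If all scores are
#' equal every topic is kept.
#'
#' @param scores Numeric vector of topic scores.
#' @param tau Threshold fraction in 0..1 (default 0.25).
#' @return A `sift_topic_scores` list: `scores`, `s_max`, `s_min`, `tau`,
#'   `relevant` (integer topic ids), `r` (their count), `cutoff`.
#' @export
select_relevant_topics <- function(scores, tau = 0.25) {
  stopifnot(length(scores) >= 1, tau >= 0, tau <= 1)
  s_max <- max(scores)
  s_min <- min(scores)
  cutoff <- (s_max - s_min) * tau + s_min
  relevant <- which(scores >= cutoff)
  structure(
    list(scores = scores, s_max = s_max, s_min = s_min, tau = tau,
         cutoff = cutoff, relevant = relevant, r = length(relevant)),
    class = "sift_topic_scores"
  )
}

#' @export
print.sift_topic_scores <- function(x, ...) {
  cat(sprintf(
    "<sift_topic_scores: %d/%d topics relevant (tau=%.2f, cutoff=%.4g)>\n",
    x$r, length(x$scores), x$tau, x$cutoff))
  invisible(x)
}

#' Filter documents by relevant-topic mass
#'
#' Keeps document m iff the probability of sampling from a relevant topic
#' meets the uniform baseline: `sum_{t in R} theta[t, m] >= r / k`, with
#' `>=` at the boundary (a uniform theta column is kept). When R contains
#' all k topics every document is kept, since theta columns sum to 1.
#'
#' @param model A `sift_lda`.
#' @param relevant Integer vector of relevant topic ids (or a
#'   `sift_topic_scores`).
#' @return Character vector of kept doc_ids, in corpus order.
#' @export
filter_documents <- function(model, relevant) {
  if (inherits(relevant, "sift_topic_scores")) relevant <- relevant$relevant
  stopifnot(length(relevant) >= 1, all(relevant >= 1),
            all(relevant <= model$k))
  mass <- colSums(model$theta[relevant, , drop = FALSE])
  colnames(model$theta)[mass >= length(relevant) / model$k - 1e-12]
}

#' N-gram enrichment table between a filtered corpus and its reference
#'
#' Applies the relevance score to all unigram, bigram, and trigram
#' occurrence counts, producing the descriptive "most/least enriched
#' phrases" report for a filtered corpus against its reference. Scores are
#' descriptive ratios, not test statistics.
#'
#' @param tok_kept,tok_ref Tokenized corpora (named token lists); kept must
#'   be a subset of ref by doc_id.
#' @param max_n Largest n-gram order (default 3).
#' @param eps Smoothing constant.
#' @param labels c(kept, ref) labels for provenance.
#' @return A `sift_relevance` tibble sorted by descending score, with a
#'   `rank` column; the tail of the table is the "least relevant" half of
#'   the report.
#' @export
ngram_enrichment <- function(tok_kept, tok_ref, max_n = 3, eps = 0.001,
                             labels = c("Di", "ref")) {
  if (!all(names(tok_kept) %in% names(tok_ref))) {
    stop("kept corpus must be a subset of the reference by doc_id",
         call. = FALSE)
  }
  ng_kept <- lapply(tok_kept, extract_ngrams, max_n = max_n)
  ng_ref <- lapply(tok_ref, extract_ngrams, max_n = max_n)
  out <- relevance_schedule(1, list(D1 = ng_kept, D0 = ng_ref),
                            labels = labels, eps = eps)
  out$rank <- seq_len(nrow(out))
  out
}

#' Write a relevance table as TSV
#'
#' @param rel A `sift_relevance`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_relevance <- function(rel, path) {
  df <- data.frame(rank = seq_len(nrow(rel)), term = rel$term,
                   score = rel$score,
                   kept = attr(rel, "kept_label"),
                   ref = attr(rel, "ref_label"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
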