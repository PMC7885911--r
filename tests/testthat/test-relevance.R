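test_that("term relevance reproduces the defining ratio on hand cases", {
  # unseen in both corpora: eps/eps = 1 exactly
  expect_equal(unname(term_relevance("x", 0, 0, 10, 110)), 1)
  # equal per-document rates: exactly 1
  expect_equal(unname(term_relevance("x", 1, 11, 10, 110)), 1)
  # term concentrated in the kept corpus
  expect_equal(unname(term_relevance("x", 2, 2, 10, 110, eps = 0.001)),
               (0.2 + 0.001) / 0.001, tolerance = 1e-12)
})

test_that("term relevance validates its inputs", {
  expect_error(term_relevance("x", 1, 2, 10, 10), "\\|B\\| > \\|A\\|")
  expect_error(term_relevance("x", -1, 2, 10, 20), "negative")
  expect_error(term_relevance("x", 3, 2, 10, 20), "f_B")
  expect_error(term_relevance("x", 1, 2, 10, 20, eps = 0), "positive")
})

test_that("term relevance is monotone in the kept-corpus count", {
  f_A <- 0:5
  r <- term_relevance(paste0("t", f_A), f_A, 5, 10, 100)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0))
})

test_that("the reference schedule picks (D1,D0) first, then (Di,D1)", {
  lists <- list(
    D0 = list(a = "x", b = "x", c = "y"),
    D1 = list(a = "x", b = "x"),
    Di = list(a = "x")
  )
  r1 <- relevance_schedule(1, lists)
  expect_equal(attr(r1, "kept_label"), "D1")
  expect_equal(attr(r1, "ref_label"), "D0")
  r3 <- relevance_schedule(3, lists)
  expect_equal(attr(r3, "kept_label"), "D3")
  expect_equal(attr(r3, "ref_label"), "D1")
  expect_error(relevance_schedule(2, lists["D0"]), "Di")
  expect_error(relevance_schedule(2, lists[c("D0", "Di")]), "D1")
})

test_that("schedule scores match brute-force recomputation over terms", {
  set.seed(12)
  vocab <- paste0("w", 1:50)
  tok_ref <- toy_tokdocs(100, vocab, seed = 12)
  kept_ids <- names(tok_ref)[sample.int(100, 20)]
  tok_kept <- tok_ref[kept_ids]
  tab <- relevance_schedule(2, list(Di = tok_kept, D1 = tok_ref))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$score[i],
                 brute_relevance(tab$term[i], tok_kept, tok_ref),
                 tolerance = 1e-12, label = tab$term[i])
  }
})

test_that("topic scores are theta-weighted means of document relevance", {
  model <- structure(
    list(k = 2,
         theta = matrix(c(0.9, 0.2, 0.1, 0.8), nrow = 2, byrow = TRUE,
                        dimnames = list(NULL, c("m1", "m2"))),
         vocabulary = c("a", "b")),
    class = "sift_lda")
  rel <- structure(tibble::tibble(term = c("a", "b"), score = c(5, 2)),
                   kept_label = "D1", ref_label = "D0", eps = 0.001)
  # doc m1 relevance sum = 2*5 = 10; m2 = 2 -> Score(t1) = 9.4/1.1
  units <- list(m1 = c("a", "a"), m2 = c("b"))
  sc <- score_topics(model, units, rel)
  expect_equal(sc[1], (0.9 * 10 + 0.2 * 2) / 1.1, tolerance = 1e-9)
  expect_equal(sc[2], (0.1 * 10 + 0.8 * 2) / 0.9, tolerance = 1e-9)

  # conceptless documents score zero everywhere
  sc0 <- score_topics(model, list(m1 = character(0), m2 = NULL), rel)
  expect_equal(sc0, c(0, 0))

  # triggers missing from the table contribute nothing
  sc_na <- score_topics(model, list(m1 = "zzz", m2 = "b"), rel)
  expect_equal(sc_na[1], (0.2 * 2) / 1.1)
})

test_that("topic scores are invariant to document order and bounded", {
  set.seed(31)
  toks <- toy_tokdocs(25, c("fever", "cough", "dog", "rain"), seed = 31)
  fit <- fit_lda(toks, k = 3, seed = 3, iterations = 100)
  rel <- relevance_schedule(2, list(Di = toks[1:10], D1 = toks))
  sc <- score_topics(fit, toks, rel)

  perm <- sample(colnames(fit$theta))
  fit2 <- fit
  fit2$theta <- fit$theta[, perm]
  sc2 <- score_topics(fit2, toks, rel)
  expect_equal(sc, sc2, tolerance = 1e-12)

  lookup <- rel$score; names(lookup) <- rel$term
  relsums <- vapply(colnames(fit$theta),
                    function(d) sum(lookup[toks[[d]]], na.rm = TRUE),
                    numeric(1))
  expect_true(all(sc >= min(relsums) - 1e-9))
  expect_true(all(sc <= max(relsums) + 1e-9))
})

test_that("topic selection thresholds with >= between min and max", {
  sel <- select_relevant_topics(c(1, 2, 3, 5), tau = 0.25)
  expect_equal(sel$cutoff, 2)
  expect_equal(sel$relevant, 2:4)
  expect_equal(sel$r, 3)

  expect_equal(select_relevant_topics(c(4, 1, 9), tau = 0)$relevant, 1:3)
  expect_equal(select_relevant_topics(c(4, 1, 9, 9), tau = 1)$relevant,
               c(3L, 4L))
  # all-equal scores keep every topic
  expect_equal(select_relevant_topics(rep(2, 5), tau = 1)$r, 5)
})

test_that("relevant-topic count is non-increasing in tau", {
  set.seed(17)
  scores <- stats::runif(40)
  taus <- seq(0, 1, by = 0.1)
  rs <- vapply(taus, function(t) select_relevant_topics(scores, t)$r,
               numeric(1))
  expect_true(all(diff(rs) <= 0))
})

test_that("document filtering keeps mass >= r/k with boundary equality", {
  theta <- matrix(c(0.5, 0.3, 0.1, 0.1,
                    0.25, 0.25, 0.25, 0.25,
                    0.05, 0.05, 0.45, 0.45), nrow = 4,
                  dimnames = list(NULL, c("m1", "m2", "m3")))
  model <- structure(list(k = 4, theta = theta), class = "sift_lda")
  # R = {1,2}: m1 has 0.8 >= 0.5 kept; m2 uniform hits equality; m3 dropped
  expect_equal(filter_documents(model, 1:2), c("m1", "m2"))
  # R = all topics keeps everything
  expect_equal(filter_documents(model, 1:4), c("m1", "m2", "m3"))
})

test_that("kept sets match brute-force application of the filter rule", {
  toks <- toy_tokdocs(30, letters[1:10], seed = 23)
  fit <- fit_lda(toks, k = 5, seed = 4, iterations = 100)
  for (r in 1:5) {
    R <- seq_len(r)
    kept <- filter_documents(fit, R)
    oracle <- colnames(fit$theta)[
      colSums(fit$theta[R, , drop = FALSE]) >= r / 5 - 1e-12]
    expect_equal(kept, oracle)
  }
  # the full topic set keeps every document
  expect_equal(filter_documents(fit, 1:5), colnames(fit$theta))
})

test_that("ngram enrichment agrees with brute-force scoring of all ngrams", {
  tok_ref <- toy_tokdocs(30, c("lung", "growth", "rate", "dog"), seed = 41,
                         min_len = 2, max_len = 5)
  tok_kept <- tok_ref[1:8]
  tab <- ngram_enrichment(tok_kept, tok_ref, max_n = 3)
  expect_true(all(diff(tab$score) <= 0))

  ng_kept <- lapply(tok_kept, extract_ngrams, max_n = 3)
  ng_ref <- lapply(tok_ref, extract_ngrams, max_n = 3)
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$score[i],
                 brute_relevance(tab$term[i], ng_kept, ng_ref),
                 tolerance = 1e-12, label = tab$term[i])
  }
  # an n-gram present only in the kept corpus scores above 1
  only_kept <- setdiff(unique(unlist(ng_kept)), unlist(ng_ref[9:30]))
  if (length(only_kept)) {
    expect_true(all(tab$score[tab$term %in% only_kept] > 1))
  }
})
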