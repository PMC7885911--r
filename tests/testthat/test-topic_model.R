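test_that("theta columns and beta rows are normalized and non-negative", {
  toks <- toy_tokdocs(30, letters[1:12], seed = 1)
  fit <- fit_lda(toks, k = 4, seed = 1, iterations = 50)
  expect_equal(colSums(fit$theta), rep(1, 30), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(rowSums(fit$beta), rep(1, 4), tolerance = 1e-6)
  expect_true(all(fit$theta >= 0))
  expect_true(all(fit$beta >= 0))
})

test_that("fits are deterministic given a seed, regardless of R's RNG", {
  toks <- toy_tokdocs(20, letters[1:8], seed = 2)
  set.seed(1); f1 <- fit_lda(toks, k = 3, seed = 7, iterations = 100)
  set.seed(999); f2 <- fit_lda(toks, k = 3, seed = 7, iterations = 100)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$beta, f2$beta)
  f3 <- fit_lda(toks, k = 3, seed = 8, iterations = 100)
  expect_false(identical(f1$theta, f3$theta))
})

test_that("zero-token documents get uniform theta columns and are flagged", {
  toks <- c(toy_tokdocs(10, letters[1:6], seed = 3),
            list(zz = character(0)))
  fit <- fit_lda(toks, k = 3, seed = 1, iterations = 50)
  expect_equal(fit$empty_docs, "zz")
  expect_equal(fit$theta[, "zz"], rep(1 / 3, 3))
  expect_error(fit_lda(list(a = character(0)), k = 2),
               "nothing to model")
})

test_that("well-separated planted topics are recovered", {
  # three disjoint 8-word vocabularies; each doc drawn from one of them
  set.seed(4)
  vocabs <- list(paste0("med", 1:8), paste0("eco", 1:8), paste0("pol", 1:8))
  toks <- lapply(1:60, function(i) {
    sample(vocabs[[(i %% 3) + 1]], 15, replace = TRUE)
  })
  names(toks) <- sprintf("p%02d", 1:60)
  fit <- fit_lda(toks, k = 3, seed = 5, iterations = 300)
  # each fitted topic's top-8 words should come from exactly one vocabulary
  assignment <- vapply(1:3, function(t) {
    tw <- top_words(fit, t, 8)
    hits <- vapply(vocabs, function(v) sum(tw %in% v), numeric(1))
    expect_equal(max(hits), 8)
    which.max(hits)
  }, numeric(1))
  expect_setequal(assignment, 1:3)
})

test_that("concept fraction counts lexicon membership of top words", {
  toks <- list(a = c("fever", "cough", "dog"), b = c("fever", "rain"))
  fit <- fit_lda(toks, k = 2, seed = 1, iterations = 50)
  lex <- tiny_lexicon()
  cf <- concept_fraction(fit, lex, n = 10)
  expect_length(cf$per_topic, 2)
  expect_equal(cf$mean, mean(cf$per_topic))
  # disjoint lexicon -> all zero; full-overlap lexicon -> counts capped by n
  disjoint <- concept_lexicon(c("xx1", "xx2"), c("C1", "C2"))
  expect_equal(concept_fraction(fit, disjoint)$per_topic, c(0, 0))
  full <- concept_lexicon(fit$vocabulary,
                          sprintf("C%d", seq_along(fit$vocabulary)))
  cf_full <- concept_fraction(fit, full, n = length(fit$vocabulary))
  expect_equal(cf_full$per_topic, rep(1, 2))
})

test_that("umass coherence matches hand-computed two-word cases", {
  # build a corpus with known document frequencies for the two top words
  # of each fitted topic, then check the formula log((D12+1)/D(w2->w1))
  docs <- list(a = c("w1", "w2"), b = c("w1", "w2"), c = c("w1", "w2"),
               d = c("w1", "x"), e = c("y", "x"))
  # D(w1)=4, D(w2)=3, D(w1,w2)=3
  model <- structure(
    list(k = 1, vocabulary = c("w1", "w2"),
         beta = matrix(c(0.6, 0.4), nrow = 1,
                       dimnames = list(NULL, c("w1", "w2"))),
         theta = matrix(1, 1, 5)),
    class = "sift_lda")
  sc <- umass_coherence(model, docs, n = 2)
  expect_equal(sc$per_topic, log((3 + 1) / 4), tolerance = 1e-9)

  # never co-occurring pair: D(w1)=5 reference, D12=0 -> log(1/5)
  docs2 <- c(lapply(1:5, function(i) "w1"), list(z = "w2"))
  names(docs2) <- sprintf("m%d", 1:6)
  model2 <- structure(
    list(k = 1, vocabulary = c("w1", "w2"),
         beta = matrix(c(0.6, 0.4), nrow = 1,
                       dimnames = list(NULL, c("w1", "w2"))),
         theta = matrix(1, 1, 6)),
    class = "sift_lda")
  sc2 <- umass_coherence(model2, docs2, n = 2)
  expect_equal(sc2$per_topic, log(1 / 5), tolerance = 1e-9)
})

test_that("umass coherence equals a brute-force pairwise loop", {
  toks <- toy_tokdocs(20, c("fever", "cough", "lung", "dog", "rain",
                            "mask", "icu", "vote"), seed = 6)
  fit <- fit_lda(toks, k = 3, seed = 2, iterations = 100)
  got <- umass_coherence(fit, toks, n = 5)

  # independent double loop straight from the definition
  brute <- vapply(1:3, function(t) {
    tw <- fit$vocabulary[order(-fit$beta[t, ], fit$vocabulary)][1:5]
    s <- 0
    for (i in 2:5) {
      for (j in 1:(i - 1)) {
        Dij <- sum(vapply(toks, function(d) {
          tw[i] %in% d && tw[j] %in% d
        }, logical(1)))
        Dj <- sum(vapply(toks, function(d) tw[j] %in% d, logical(1)))
        s <- s + log((Dij + 1) / if (Dj > 0) Dj else 1)
      }
    }
    s
  }, numeric(1))
  expect_equal(got$per_topic, brute, tolerance = 1e-9)
})

test_that("model dumps write theta and ranked top words", {
  toks <- toy_tokdocs(10, letters[1:6], seed = 8)
  fit <- fit_lda(toks, k = 2, seed = 1, iterations = 50)
  dir <- withr::local_tempdir()
  write_lda(fit, dir)
  theta <- utils::read.delim(file.path(dir, "theta.tsv"))
  expect_equal(dim(theta), c(2, 10))
  tw <- utils::read.delim(file.path(dir, "top_words.tsv"))
  expect_equal(unique(tw$topic_id), 1:2)
  expect_true(all(diff(tw$weight[tw$topic_id == 1]) <= 0))
})
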