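test_that("a 28-day range yields three full overlapping windows", {
  x <- make_corpus(3)
  wins <- split_windows(x, "2020-03-01", "2020-03-29")
  expect_length(wins, 3)
  expect_equal(wins[[1]]$start, as.Date("2020-03-01"))
  expect_equal(wins[[1]]$end, as.Date("2020-03-15"))
  expect_equal(wins[[3]]$start, as.Date("2020-03-15"))
  expect_equal(wins[[3]]$end, as.Date("2020-03-29"))
})

test_that("boundary-day documents join the opening window only", {
  x <- corpus(doc_id = "a", text = "t",
              created_at = "2020-03-15T00:00:00Z")
  wins <- split_windows(x, "2020-03-01", "2020-03-29")
  member <- vapply(wins, function(w) corpus_size(w$corpus) == 1,
                   logical(1))
  # day 14 closes window 1 (half-open) but opens window 3
  expect_equal(member, c(FALSE, TRUE, TRUE))
})

test_that("every in-range document lands in one or two windows", {
  x <- random_corpus(60, seed = 77)
  wins <- split_windows(x, "2020-03-01", "2020-03-29")
  counts <- table(unlist(lapply(wins, function(w) w$corpus$doc_id)))
  in_range <- x$doc_id[as.Date(x$created_at) >= as.Date("2020-03-01") &
                         as.Date(x$created_at) < as.Date("2020-03-29")]
  expect_true(all(counts %in% 1:2))
  # documents in the doubly-covered middle region appear twice
  expect_setequal(names(counts), intersect(in_range, names(counts)))
  expect_equal(length(split_windows(corpus(character(), character()),
                                    "2020-03-01", "2020-03-29")), 3)
})

test_that("keyword trends report counts, first date, and window flags", {
  x <- corpus(
    doc_id = c("a", "b", "c"), text = c("anosmia case", "normal day",
                                        "anosmia and dysgeusia"),
    created_at = c("2020-03-20T10:00:00Z", "2020-03-05T10:00:00Z",
                   "2020-03-25T10:00:00Z"))
  tr <- keyword_trend(list(), x, "anosmi[a-z]*")
  expect_equal(tr$first_date, as.Date("2020-03-20"))
  expect_equal(sum(tr$weekly$count), 2)

  none <- keyword_trend(list(), x, "zzznever")
  expect_true(is.na(none$first_date))
  expect_equal(nrow(none$weekly), 0)

  expect_error(keyword_trend(list(), x, "(unclosed"), "unclosed")
})

test_that("a planted post-onset topic only surfaces after its onset", {
  spec <- generator_spec(
    n_docs = 600, n_clinical = 60, n_general = 120, seed = 42,
    date_start = "2020-03-01", date_end = "2020-04-30",
    trend_events = list(list(topic = 3, onset = "2020-03-31")))
  g <- generate_corpus(spec)
  phi <- g$topics
  sig <- colnames(phi)[phi[3, ] > 0 & colSums(phi[-3, , drop = FALSE]) == 0]
  sig <- sig[order(-phi[3, sig])][1:5]

  wins <- split_windows(g$corpus, "2020-03-01", "2020-04-30")
  cfg <- pipeline_config(k = 10, max_iterations = 2, lexicon = g$lexicon,
                         gibbs_iterations = 300, seed = 42,
                         stop_topic_fraction = 1)
  wres <- windowed_topics(wins, cfg)
  onset <- as.Date("2020-03-31")
  for (res in wres) {
    hit <- any(sig %in% unlist(res$top_words))
    if (res$window$end <= onset) {
      expect_false(hit, label = res$window$label)
    }
  }
  # the trend must surface somewhere post-onset
  post <- Filter(function(res) res$window$end > onset, wres)
  expect_true(any(vapply(post, function(res) {
    any(sig %in% unlist(res$top_words))
  }, logical(1))))

  tr <- keyword_trend(wres, g$corpus, paste0("\\b", sig, "\\b"))
  expect_gte(tr$first_date, onset)
  flagged_ends <- vapply(wres, function(res) res$window$end, numeric(1))
  names(flagged_ends) <- vapply(wres, function(res) res$window$label,
                                character(1))
  expect_true(all(as.Date(flagged_ends[tr$windows],
                          origin = "1970-01-01") > onset))
})

test_that("windowed runs are deterministic per window", {
  g <- generate_corpus(generator_spec(n_docs = 300, n_clinical = 40,
                                      n_general = 80, seed = 9))
  wins <- split_windows(g$corpus, "2020-03-01", "2020-03-29")
  cfg <- pipeline_config(k = 8, max_iterations = 1, lexicon = g$lexicon,
                         gibbs_iterations = 100, seed = 9,
                         stop_topic_fraction = 1)
  a <- windowed_topics(wins, cfg)
  b <- windowed_topics(wins, cfg)
  expect_identical(lapply(a, `[[`, "top_words"),
                   lapply(b, `[[`, "top_words"))
})

test_that("category membership needs two distinct matching patterns", {
  x <- corpus(
    doc_id = c("a", "b", "c"),
    text = c("anosmia with dysgeusia reported",
             "anosmia alone here",
             "no symptoms at all"))
  cat_smell <- keyword_category("smell", c("anosmi[a-z]*", "dysgeusi[a-z]*"))
  expect_error(keyword_category("bad", "only-one"), "at least 2")

  g <- generate_corpus(generator_spec(n_docs = 300, n_clinical = 40,
                                      n_general = 80, seed = 10))
  cfg <- pipeline_config(k = 8, max_iterations = 2, lexicon = g$lexicon,
                         gibbs_iterations = 150, seed = 10,
                         stop_topic_fraction = 1)
  run <- run_pipeline(g$corpus, cfg)
  # clinical words co-occur in relevant docs; absent pairs give NA
  cats <- list(
    keyword_category("clinical", c("clin001", "clin002", "clin003",
                                   "clin004", "clin005", "clin006")),
    keyword_category("absent", c("zz1", "zz2"))
  )
  ret <- category_retention(run, cats)
  expect_equal(ret$category, c("clinical", "absent"))
  expect_true(is.na(ret$iter_1[ret$category == "absent"]))
  fr <- as.numeric(ret[ret$category == "clinical",
                       grep("^iter_", names(ret))])
  expect_true(all(fr >= 0 & fr <= 1, na.rm = TRUE))
  expect_true(all(diff(fr) <= 1e-12))

  # direct membership check on the tiny corpus
  members <- topicsift:::category_members(x, cat_smell)
  expect_equal(members, "a")
})

test_that("relevant categories are retained better than irrelevant ones", {
  g <- generate_corpus(generator_spec(seed = 3))
  cfg <- pipeline_config(k = 20, max_iterations = 2, lexicon = g$lexicon,
                         gibbs_iterations = 400, seed = 3,
                         stop_topic_fraction = 1)
  run <- run_pipeline(g$corpus, cfg)
  clin <- paste0("clin", sprintf("%03d", 1:40))
  gen <- paste0("gen", sprintf("%03d", 1:40))
  cats <- list(keyword_category("relevant_terms", clin),
               keyword_category("irrelevant_terms", gen))
  ret <- category_retention(run, cats)
  last <- paste0("iter_", length(run$states))
  expect_gt(ret[[last]][1], ret[[last]][2])
})
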