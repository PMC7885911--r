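#' Split a corpus into overlapping time windows
#'
#' Windows are 14 days wide at a 7-day stride (so successive windows
#' overlap by one week), anchored at `start`, half-open `[start, end)` in
#' UTC, and clipped to the requested range: only windows lying entirely
#' inside `[start, end)` are produced. A document on a boundary day belongs
#' to the window opening that day, not the one closing.
#'
#' @param x A `sift_corpus`.
#' @param start,end Dates (or parseable strings) bounding the analysis.
#' @param width_days,stride_days Window geometry (defaults 14 and 7).
#' @return A list of windows; each has `start`, `end` (Dates), `label`,
#'   and `corpus` (the sub-corpus of documents whose timestamp falls in
#'   the window).
#' @export
split_windows <- function(x, start, end, width_days = 14, stride_days = 7) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (!start < end) stop("start must precede end", call. = FALSE)
  starts <- seq(start, end, by = stride_days)
  starts <- starts[starts + width_days <= end]
  days <- as.Date(x$created_at)
  lapply(seq_along(starts), function(w) {
    s <- starts[w]
    e <- s + width_days
    inside <- !is.na(days) & days >= s & days < e
    list(start = s, end = e,
         label = sprintf("%s/%s", format(s), format(e)),
         corpus = new_corpus(x[inside, , drop = FALSE],
                             sprintf("W%02d", w)))
  })
}

#' Fit relevance-filtered topic models per time window
#'
#' Runs the full iterative pipeline (author filter included) independently
#' on each window's sub-corpus — typically with `max_iterations = 2`, which
#' is enough filtering for a two-week slice — and records the final
#' iteration's model, topic scores, and per-topic top-10 words. Window w
#' uses `config$seed + 1000 * w` so windows are reproducible yet
#' independently seeded. Empty windows are skipped with a warning.
#'
#' @param windows Output of [split_windows()].
#' @param config A `sift_config`.
#' @param n_words Top words recorded per topic (default 10).
#' @param verbose Progress messages.
#' @return A list per window: `window` (label/start/end), `run`
#'   (`sift_run`), `top_words` (list of character vectors per topic).
#'   Skipped windows are dropped.
#' @export
windowed_topics <- function(windows, config, n_words = 10,
                            verbose = FALSE) {
  out <- list()
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    if (corpus_size(win$corpus) == 0) {
      warning("window ", win$label, " is empty; skipped", call. = FALSE)
      next
    }
    cfg <- config
    cfg$seed <- config$seed + 1000L * w
    run <- tryCatch(
      run_pipeline(win$corpus, cfg),
      error = function(e) {
        stop("window ", win$label, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    last <- run$states[[length(run$states)]]
    tw <- lapply(seq_len(last$model$k), function(t) {
      top_words(last$model, t, n_words)
    })
    if (verbose) {
      message(sprintf("window %s: M=%d, r=%d", win$label,
                      corpus_size(win$corpus), last$topic_scores$r))
    }
    out[[length(out) + 1L]] <- list(
      window = win[c("start", "end", "label")], run = run, top_words = tw
    )
  }
  out
}

#' Keyword timelines against windowed topic models
#'
#' For a set of case-insensitive regular expressions describing one
#' clinical keyword group: weekly counts of matching documents, the date
#' of the first matching document, and the windows whose topic models
#' surface the keyword (a match inside any topic's recorded top words).
#'
#' @param wresults Output of [windowed_topics()].
#' @param x The full `sift_corpus` searched for raw-text matches.
#' @param patterns Character vector of regular expressions.
#' @return List with `weekly` (tibble `week_start`, `count`),
#'   `first_date` (Date or NA), and `windows` (labels of windows whose
#'   top words match).
#' @export
keyword_trend <- function(wresults, x, patterns) {
  for (p in patterns) {
    ok <- tryCatch({suppressWarnings(grepl(p, "", perl = TRUE)); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("invalid regular expression: '", p, "'", call. = FALSE)
  }
  hits <- rep(FALSE, corpus_size(x))
  for (p in patterns) {
    hits <- hits | grepl(p, x$text, ignore.case = TRUE, perl = TRUE)
  }
  days <- as.Date(x$created_at)
  hit_days <- days[hits & !is.na(days)]
  first_date <- if (length(hit_days)) min(hit_days) else as.Date(NA)
  weekly <- if (length(hit_days)) {
    wk <- hit_days - as.numeric(hit_days - min(days, na.rm = TRUE)) %% 7
    agg <- table(format(wk))
    tibble::tibble(week_start = as.Date(names(agg)),
                   count = as.numeric(agg))
  } else {
    tibble::tibble(week_start = as.Date(character()), count = numeric())
  }
  win_hit <- vapply(wresults, function(res) {
    words <- unlist(res$top_words, use.names = FALSE)
    any(vapply(patterns,
               function(p) any(grepl(p, words, ignore.case = TRUE,
                                     perl = TRUE)),
               logical(1)))
  }, logical(1))
  list(weekly = weekly, first_date = first_date,
       windows = vapply(wresults[win_hit],
                        function(res) res$window$label, character(1)))
}

#' Define keyword categories for retention analysis
#'
#' @param name Category name.
#' @param patterns At least two case-insensitive regular expressions; a
#'   document belongs to the category only if two *distinct* patterns
#'   match, which makes membership a reliable relevance gauge.
#' @return A `sift_category` list.
#' @export
keyword_category <- function(name, patterns) {
  if (length(patterns) < 2) {
    stop("category '", name, "' needs at least 2 patterns", call. = FALSE)
  }
  structure(list(name = name, patterns = patterns),
            class = "sift_category")
}

category_members <- function(x, category) {
  nmatch <- rep(0L, corpus_size(x))
  text <- tolower(x$text)
  for (p in category$patterns) {
    nmatch <- nmatch + grepl(p, text, ignore.case = TRUE, perl = TRUE)
  }
  x$doc_id[nmatch >= 2]
}

#' Category retention across filtering iterations
#'
#' For each keyword category, the fraction of its D1 members still present
#' in the kept set after each iteration:
#' `|category members kept at i| / |category members in D1|`. Because kept
#' sets are nested, fractions are non-increasing in i. Categories with no
#' members in D1 are reported as NA. Matching runs on raw lowercase text
#' (not the normalized tokens) so multiword and inflected keywords behave
#' as written.
#'
#' @param run A `sift_run`.
#' @param categories List of [keyword_category()] objects.
#' @return Tibble with `category`, `n_d1` (members in D1), and one
#'   `iter_<i>` column per iteration.
#' @export
category_retention <- function(run, categories) {
  stopifnot(length(run$states) >= 1)
  d1 <- run$d1
  rows <- lapply(categories, function(cat) {
    members <- category_members(d1, cat)
    denom <- length(members)
    fracs <- vapply(run$states, function(st) {
      if (denom == 0) return(NA_real_)
      sum(members %in% st$kept_ids) / denom
    }, numeric(1))
    row <- tibble::tibble(category = cat$name, n_d1 = denom)
    for (i in seq_along(fracs)) row[[paste0("iter_", i)]] <- fracs[i]
    row
  })
  do.call(rbind, rows)
}
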