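#' Pipeline configuration
#'
#' Collects every tunable of the iterative relevance filter with the
#' method's defaults: k = 100 topics, tau = 0.25, eps = 0.001, up to 3
#' filtering iterations with an early stop once at least half the topics
#' are scored relevant (by then most irrelevant content is gone and
#' further filtering has little to remove).
#'
#' @param k Topic count (>= 2); default 100.
#' @param tau Topic-score threshold fraction in 0..1; default 0.25.
#' @param eps Relevance smoothing constant; default 0.001.
#' @param max_iterations Filtering rounds; default 3.
#' @param relevance_basis `"concepts"` (score concept triggers) or
#'   `"all_words"` (score every token; the concept-free variant).
#' @param seed Integer seed; iteration i refits LDA from scratch with
#'   seed + i - 1.
#' @param stop_topic_fraction Early-stop fraction of k; default 0.5.
#' @param lexicon A `sift_lexicon` for annotation (default the bundled toy
#'   ontology); ignored under `all_words`.
#' @param hcp_patterns Credential lexicon for the author filter.
#' @param stopwords,query_terms Token filters for preprocessing.
#' @param gibbs_iterations,alpha,eta LDA sampler controls; `alpha = NULL`
#'   means 5/k.
#' @return A `sift_config` list.
#' @export
pipeline_config <- function(k = 100, tau = 0.25, eps = 0.001,
                            max_iterations = 3,
                            relevance_basis = c("concepts", "all_words"),
                            seed = 13, stop_topic_fraction = 0.5,
                            lexicon = NULL,
                            hcp_patterns = hcp_lexicon(),
                            stopwords = default_stopwords(),
                            query_terms = default_query_terms(),
                            gibbs_iterations = 1000, alpha = NULL,
                            eta = 0.01) {
  relevance_basis <- match.arg(relevance_basis)
  stopifnot(k >= 2, tau >= 0, tau <= 1, eps > 0, max_iterations >= 1,
            stop_topic_fraction > 0, stop_topic_fraction <= 1)
  structure(
    list(k = k, tau = tau, eps = eps, max_iterations = max_iterations,
         relevance_basis = relevance_basis, seed = as.integer(seed),
         stop_topic_fraction = stop_topic_fraction, lexicon = lexicon,
         hcp_patterns = hcp_patterns, stopwords = stopwords,
         query_terms = query_terms,
         gibbs_iterations = gibbs_iterations,
         alpha = if (is.null(alpha)) 5 / k else alpha, eta = eta),
    class = "sift_config"
  )
}

#' Read a flat key = value configuration file
#'
#' Recognized keys mirror [pipeline_config()] arguments; `lexicon`,
#' `hcp_patterns`, `stopwords`, and `query_terms` take file paths.
#'
#' @param path Configuration file.
#' @return A `sift_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*[:=]\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = ":"), character(1))
  get <- function(key) if (key %in% keys) vals[match(key, keys)] else NULL
  num <- function(key, default) {
    v <- get(key); if (is.null(v)) default else as.numeric(v)
  }
  args <- list(
    k = num("k", 100), tau = num("tau", 0.25), eps = num("eps", 0.001),
    max_iterations = num("max_iterations", 3),
    relevance_basis = get("relevance_basis") %||% "concepts",
    seed = num("seed", 13),
    stop_topic_fraction = num("stop_topic_fraction", 0.5),
    gibbs_iterations = num("gibbs_iterations", 1000),
    eta = num("eta", 0.01)
  )
  if (!is.null(get("alpha"))) args$alpha <- num("alpha", NULL)
  if (!is.null(get("lexicon"))) {
    args$lexicon <- read_concept_lexicon(get("lexicon"))
  }
  if (!is.null(get("hcp_patterns"))) {
    args$hcp_patterns <- read_hcp_lexicon(get("hcp_patterns"))
  }
  if (!is.null(get("stopwords"))) {
    args$stopwords <- read_term_list(get("stopwords"))
  }
  if (!is.null(get("query_terms"))) {
    args$query_terms <- read_term_list(get("query_terms"))
  }
  do.call(pipeline_config, args)
}

#' Run the iterative relevance-filtering pipeline
#'
#' The full method: the raw corpus D0 is reduced to D1 by the
#' healthcare-professional author heuristic; then each iteration i fits a
#' k-topic LDA model on the current corpus, scores concept triggers by
#' their kept-versus-reference rate ratio (D1 against D0 at i = 1, the
#' current corpus against the fixed D1 baseline afterwards), scores topics
#' by the theta-weighted relevance of their documents' concepts, keeps the
#' topics above the tau cutoff, and keeps the documents whose relevant-topic
#' mass meets the uniform baseline r/k. Under the `concepts` basis a
#' one-time pre-filter first discards concepts that are not enriched in D1
#' relative to D0 (Rel < 1); the removal persists for the whole run.
#' Iteration ends after `max_iterations` rounds or as soon as the number of
#' relevant topics reaches `stop_topic_fraction * k`.
#'
#' @param d0 The raw `sift_corpus` (non-empty). The corpus must contain
#'   both matching and non-matching authors: iteration-1 relevance compares
#'   the author-filtered subset against the documents the filter discarded,
#'   so a corpus that is already 100% credentialed has no reference set.
#' @param config A `sift_config`.
#' @param verbose Print one progress line per iteration.
#' @return A `sift_run` list: `final` (the last filtered corpus),
#'   `states` (one record per iteration: `i`, `label`, `M`, `model`,
#'   `topic_scores`, `kept_ids`, `relevance`), `d1`, `config`,
#'   `removed_triggers`, `stopped_early`.
#' @export
run_pipeline <- function(d0, config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "sift_config"))
  if (corpus_size(d0) == 0) stop("D0 is empty", call. = FALSE)
  d0 <- set_corpus_label(d0, "D0")
  d1 <- filter_hcp(d0, config$hcp_patterns)
  if (corpus_size(d1) == 0) {
    stop("author filter kept no documents: nothing to model", call. = FALSE)
  }
  if (corpus_size(d1) == corpus_size(d0)) {
    stop("author filter discarded nothing: iteration-1 relevance needs a ",
         "non-empty reference set of non-credentialed documents",
         call. = FALSE)
  }
  tok_d0 <- tokenize_corpus(d0, config$query_terms, config$stopwords)
  tok_d1 <- tok_d0[d1$doc_id]

  removed_triggers <- character(0)
  if (config$relevance_basis == "concepts") {
    lexicon <- config$lexicon %||% toy_concept_lexicon()
    mentions_d0 <- annotate(tok_d0, lexicon)
    mentions_d1 <- mentions_d0[mentions_d0$doc_id %in% d1$doc_id, ,
                               drop = FALSE]
    pre <- prefilter_concepts(mentions_d1, tok_d1, tok_d0, lexicon,
                              eps = config$eps)
    removed_triggers <- attr(pre, "removed_triggers")
    mentions_d0 <- mentions_d0[!mentions_d0$trigger %in% removed_triggers, ,
                               drop = FALSE]
    units_d0 <- mentions_by_doc(mentions_d0, d0$doc_id)
  } else {
    units_d0 <- tok_d0
  }
  units_d1 <- units_d0[d1$doc_id]

  states <- list()
  current <- d1
  stopped_early <- FALSE
  for (i in seq_len(config$max_iterations)) {
    if (corpus_size(current) == 0) {
      stop("iteration ", i, ": corpus is empty, cannot continue",
           call. = FALSE)
    }
    tok_i <- tok_d0[current$doc_id]
    units_i <- units_d0[current$doc_id]
    rel <- if (i == 1) {
      relevance_schedule(1, list(D1 = units_d1, D0 = units_d0),
                         eps = config$eps)
    } else {
      relevance_schedule(i, list(Di = units_i, D1 = units_d1),
                         eps = config$eps)
    }
    model <- fit_lda(tok_i, k = config$k,
                     seed = config$seed + i - 1L,
                     alpha = config$alpha, eta = config$eta,
                     iterations = config$gibbs_iterations)
    scores <- score_topics(model, units_i, rel)
    sel <- select_relevant_topics(scores, tau = config$tau)
    kept_ids <- filter_documents(model, sel)
    states[[i]] <- list(
      i = i, label = corpus_label(current), M = corpus_size(current),
      model = model, topic_scores = sel, kept_ids = kept_ids,
      relevance = rel
    )
    if (verbose) {
      message(sprintf(
        "iteration %d: %s (M=%d) -> kept %d docs, r=%d/%d topics [%.3g, %.3g]",
        i, corpus_label(current), corpus_size(current), length(kept_ids),
        sel$r, config$k, sel$s_min, sel$s_max))
    }
    current <- corpus_subset(current, kept_ids, label = paste0("D", i + 1))
    if (sel$r >= config$stop_topic_fraction * config$k) {
      stopped_early <- i < config$max_iterations
      break
    }
  }
  structure(
    list(final = current, states = states, d1 = d1, config = config,
         removed_triggers = removed_triggers,
         stopped_early = stopped_early),
    class = "sift_run"
  )
}

#' @export
print.sift_run <- function(x, ...) {
  sizes <- vapply(x$states, `[[`, numeric(1), "M")
  cat(sprintf("<sift_run: %d iteration(s), %s -> %d documents>\n",
              length(x$states),
              paste(sizes, collapse = " -> "), corpus_size(x$final)))
  invisible(x)
}

#' Per-topic daily intensity
#'
#' For one iteration's model, sums theta over the kept documents of each
#' calendar (UTC) day: `intensity[t, day] = sum_{m kept, day(m)=day}
#' theta[t, m]`. Total intensity over all topics and days equals the total
#' theta mass of the kept documents.
#'
#' @param state One element of `run$states`.
#' @param corpus The corpus the state's model was fitted on (provides
#'   timestamps); `run$d1` works for every iteration since kept sets nest.
#' @return Tibble with `topic`, `day` (Date), `intensity`.
#' @export
topic_intensity <- function(state, corpus) {
  kept <- state$kept_ids
  theta <- state$model$theta[, kept, drop = FALSE]
  days <- as.Date(corpus$created_at[match(kept, corpus$doc_id)])
  rows <- list()
  for (t in seq_len(nrow(theta))) {
    agg <- tapply(theta[t, ], days, sum)
    rows[[t]] <- tibble::tibble(
      topic = t, day = as.Date(names(agg)), intensity = as.numeric(agg)
    )
  }
  do.call(rbind, rows)
}

#' Human-readable run summary
#'
#' Per iteration: corpus label and size, relevant-topic count and score
#' range, and the topics ranked by descending score with their top-10
#' words and relevance flags.
#'
#' @param run A `sift_run`.
#' @param n_words Words shown per topic.
#' @param n_topics Topics shown per iteration (default all).
#' @return Character vector of report lines (invisibly printable via
#'   `cat(report(run), sep = "\n")`).
#' @export
report <- function(run, n_words = 10, n_topics = NULL) {
  stopifnot(length(run$states) >= 1)
  out <- character(0)
  sizes <- vapply(run$states, `[[`, numeric(1), "M")
  out <- c(out, sprintf("Corpus trajectory: %s -> %d documents",
                        paste(sprintf("%s=%d",
                                      vapply(run$states, `[[`,
                                             character(1), "label"),
                                      sizes), collapse = " -> "),
                        corpus_size(run$final)))
  for (st in run$states) {
    sel <- st$topic_scores
    out <- c(out, sprintf(
      "Iteration %d (%s, M=%d): r=%d relevant topics, scores [%.4g, %.4g]",
      st$i, st$label, st$M, sel$r, sel$s_min, sel$s_max))
    ord <- order(-sel$scores)
    if (!is.null(n_topics)) ord <- ord[seq_len(min(n_topics, length(ord)))]
    for (t in ord) {
      out <- c(out, sprintf(
        "  topic %3d  score %10.4f  %s  %s",
        t, sel$scores[t],
        if (t %in% sel$relevant) "[relevant]  " else "[irrelevant]",
        paste(top_words(st$model, t, n_words), collapse = " ")))
    }
  }
  out
}

#' Write a run's outputs to a directory
#'
#' Emits, per iteration, the model dump, topic scores, relevance table and
#' kept-document list, plus the final corpus and a manifest.
#'
#' @param run A `sift_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in run$states) {
    sub <- file.path(dir, sprintf("iteration_%d", st$i))
    dir.create(sub, showWarnings = FALSE)
    write_lda(st$model, sub)
    sel <- st$topic_scores
    utils::write.table(
      data.frame(topic = seq_along(sel$scores), score = sel$scores,
                 relevant = seq_along(sel$scores) %in% sel$relevant),
      file.path(sub, "topic_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_relevance(st$relevance, file.path(sub, "relevance.tsv"))
    writeLines(st$kept_ids, file.path(sub, "kept_ids.txt"))
  }
  write_corpus(run$final, file.path(dir, "final_corpus.jsonl"))
  manifest <- c(
    sprintf("iterations\t%d", length(run$states)),
    sprintf("final_size\t%d", corpus_size(run$final)),
    sprintf("stopped_early\t%s", run$stopped_early),
    sprintf("relevance_basis\t%s", run$config$relevance_basis),
    sprintf("k\t%d", run$config$k),
    sprintf("tau\t%g", run$config$tau),
    sprintf("seed\t%d", run$config$seed)
  )
  writeLines(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
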