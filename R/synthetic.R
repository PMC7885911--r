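#' Specification for a synthetic evaluation corpus
#'
#' Describes a mixed corpus emulating the statistical structure the
#' filtering method assumes: a minority of "relevant" documents drawn
#' mostly from clinical planted topics over a concept vocabulary, authored
#' largely by credentialed users, against a majority of noise documents
#' that share surface vocabulary with the clinical ones (controlled by
#' `overlap`). The generator provides ground-truth labels, so filtering
#' precision and recall are measurable — something the method's real
#' target corpora never allow.
#'
#' @param n_docs Number of documents (default 2000).
#' @param k_true Planted topic count (default 10).
#' @param clinical_topics Indices of the clinical planted topics
#'   (default 1:3).
#' @param n_clinical,n_general Vocabulary sizes (defaults 200 and 400).
#' @param doc_length Mean tokens per document (Poisson; default 18).
#' @param dirichlet_alpha Concentration of the per-document topic mixture
#'   (default 0.3).
#' @param relevant_fraction Target share of documents whose clinical-topic
#'   mass is at least 0.5 (default 0.25).
#' @param overlap Fraction of clinical words that also receive mass in
#'   noise topics (default 0.2): the "mundane posts reuse clinical
#'   vocabulary" effect that makes filtering non-trivial.
#' @param hcp_bio_rate_relevant,hcp_bio_rate_noise Probability that the
#'   author bio carries a credential keyword, per document class (defaults
#'   0.9 and 0.2, chosen so the author-filtered corpus is roughly 60%
#'   relevant — a deliberately imperfect first filter).
#' @param n_style,style_mean Community-jargon vocabulary: documents by
#'   credentialed authors mix in on average `style_mean` tokens (Poisson)
#'   drawn from `n_style` jargon words, regardless of relevance class
#'   (defaults 20 and 2). These emulate the hashtags and community markers
#'   that are strongly enriched among professional authors yet carry no
#'   clinical content, which is what separates concept-based from
#'   all-words relevance scoring on real data.
#' @param date_start,date_end UTC date range for timestamps (defaults
#'   2020-03-01 to 2020-04-30).
#' @param trend_events Optional list of `list(topic =, onset =)` entries:
#'   documents that drew any tokens from a trend topic are timestamped
#'   only from `onset` on.
#' @param seed Integer seed; fixed seed gives byte-identical corpora.
#' @return A `sift_genspec` list.
#' @export
generator_spec <- function(n_docs = 2000, k_true = 10,
                           clinical_topics = 1:3,
                           n_clinical = 200, n_general = 400,
                           doc_length = 18, dirichlet_alpha = 0.3,
                           relevant_fraction = 0.25, overlap = 0.2,
                           hcp_bio_rate_relevant = 0.9,
                           hcp_bio_rate_noise = 0.2,
                           n_style = 20, style_mean = 2,
                           date_start = "2020-03-01",
                           date_end = "2020-04-30",
                           trend_events = NULL, seed = 1) {
  stopifnot(n_docs >= 1, k_true >= 2,
            all(clinical_topics %in% seq_len(k_true)) ||
              length(clinical_topics) == 0,
            relevant_fraction >= 0, relevant_fraction <= 1,
            overlap >= 0, overlap <= 1,
            hcp_bio_rate_relevant >= 0, hcp_bio_rate_relevant <= 1,
            hcp_bio_rate_noise >= 0, hcp_bio_rate_noise <= 1)
  if (relevant_fraction > 0 && length(clinical_topics) == 0) {
    stop("relevant_fraction > 0 requires at least one clinical topic",
         call. = FALSE)
  }
  if (length(clinical_topics) >= k_true) {
    stop("at least one non-clinical topic is required", call. = FALSE)
  }
  structure(
    list(n_docs = n_docs, k_true = k_true,
         clinical_topics = clinical_topics,
         n_clinical = n_clinical, n_general = n_general,
         doc_length = doc_length, dirichlet_alpha = dirichlet_alpha,
         relevant_fraction = relevant_fraction, overlap = overlap,
         hcp_bio_rate_relevant = hcp_bio_rate_relevant,
         hcp_bio_rate_noise = hcp_bio_rate_noise,
         n_style = n_style, style_mean = style_mean,
         date_start = as.Date(date_start), date_end = as.Date(date_end),
         trend_events = trend_events, seed = as.integer(seed)),
    class = "sift_genspec"
  )
}

credential_bios <- c(
  "Emergency physician, MD, views my own",
  "RN in the ICU, tweets about medicine",
  "Dr and hospitalist, academic medicine",
  "public health researcher and epidemiologist",
  "Infectious disease doc, MD PhD",
  "pediatric nurse and educator"
)

noise_bios <- c(
  "love cooking, travel and my dog",
  "sports fan and amateur photographer",
  "startup founder, coffee enthusiast",
  "music, movies and hot takes",
  "parent of three, gardening on weekends",
  "crypto watcher and gamer"
)

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Each document draws a topic mixture from a Dirichlet (boosted on
#' clinical topics for the intended-relevant share of documents, supported
#' only on noise topics otherwise), then draws Poisson-many tokens from
#' the planted topic-word distributions. A document is labeled `relevant`
#' iff its clinical-topic mass is at least 0.5. Author bios carry a
#' credential keyword at the class-dependent rate; timestamps are uniform
#' over the date range except for documents that emitted tokens of a
#' trend topic, which are stamped only after the trend's onset. Clinical words appear
#' at strictly higher per-document rates in relevant documents, which is
#' exactly the signal the relevance score estimates.
#'
#' @param spec A `sift_genspec`.
#' @return List with `corpus` (a `sift_corpus` labeled "D0"), `truth`
#'   (named character vector: doc_id -> "relevant"/"irrelevant"),
#'   `lexicon` (a `sift_lexicon` covering every clinical word), and
#'   `topics` (the planted topic-word matrix, rows = topics).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "sift_genspec"))
  with_seed(spec$seed, {
    clin_words <- sprintf("clin%03d", seq_len(spec$n_clinical))
    gen_words <- sprintf("gen%03d", seq_len(spec$n_general))
    vocab <- c(clin_words, gen_words)
    V <- length(vocab)
    K <- spec$k_true
    clin_ids <- spec$clinical_topics
    noise_ids <- setdiff(seq_len(K), clin_ids)

    # planted topic-word distributions: clinical topics over a partition of
    # the clinical vocabulary, noise topics over a partition of the general
    # vocabulary plus a down-weighted slice of overlapping clinical words
    phi <- matrix(0, nrow = K, ncol = V, dimnames = list(NULL, vocab))
    clin_parts <- split(seq_len(spec$n_clinical),
                        rep_len(seq_along(clin_ids), spec$n_clinical))
    for (j in seq_along(clin_ids)) {
      idx <- clin_parts[[j]]
      phi[clin_ids[j], idx] <- rdirichlet1(rep(0.1, length(idx)))
    }
    gen_parts <- split(spec$n_clinical + seq_len(spec$n_general),
                       rep_len(seq_along(noise_ids), spec$n_general))
    n_overlap <- round(spec$overlap * spec$n_clinical)
    overlap_words <- if (n_overlap > 0) {
      sample(seq_len(spec$n_clinical), n_overlap)
    } else integer(0)
    for (j in seq_along(noise_ids)) {
      idx <- gen_parts[[j]]
      w <- rdirichlet1(rep(0.1, length(idx)))
      phi[noise_ids[j], idx] <- w
      if (n_overlap > 0) {
        # overlapping clinical words get ~20% of each noise topic's mass
        ov <- rdirichlet1(rep(0.1, n_overlap)) * 0.25
        phi[noise_ids[j], overlap_words] <-
          phi[noise_ids[j], overlap_words] + ov
        phi[noise_ids[j], ] <- phi[noise_ids[j], ] /
          sum(phi[noise_ids[j], ])
      }
    }

    # per-document topic mixtures: intended-relevant documents lean on the
    # clinical topics but stay genuine mixtures (drawn conditional on
    # majority clinical mass, so the label matches the intent and the
    # labeled share concentrates on relevant_fraction); intended-noise
    # documents carry a weak clinical component, conditioned below 0.5
    n <- spec$n_docs
    intended <- stats::runif(n) < spec$relevant_fraction
    theta <- matrix(0, nrow = n, ncol = K)
    for (d in seq_len(n)) {
      if (intended[d]) {
        a <- rep(spec$dirichlet_alpha, K)
        a[clin_ids] <- 2
        repeat {
          mix <- rdirichlet1(a)
          if (sum(mix[clin_ids]) >= 0.5) break
        }
      } else {
        a <- rep(spec$dirichlet_alpha + 0.2, K)
        a[clin_ids] <- spec$dirichlet_alpha / 3
        repeat {
          mix <- rdirichlet1(a)
          if (sum(mix[clin_ids]) < 0.5) break
        }
      }
      theta[d, ] <- mix
    }
    clin_mass <- rowSums(theta[, clin_ids, drop = FALSE])
    truth <- ifelse(clin_mass >= 0.5, "relevant", "irrelevant")

    hcp_rate <- ifelse(truth == "relevant",
                       spec$hcp_bio_rate_relevant,
                       spec$hcp_bio_rate_noise)
    has_cred <- stats::runif(n) < hcp_rate
    bios <- ifelse(has_cred,
                   sample(credential_bios, n, replace = TRUE),
                   sample(noise_bios, n, replace = TRUE))
    style_vocab <- sprintf("jarg%02d", seq_len(spec$n_style))

    lens <- pmax(3, stats::rpois(n, spec$doc_length))
    texts <- character(n)
    used_topics <- vector("list", n)
    for (d in seq_len(n)) {
      zs <- sample.int(K, lens[d], replace = TRUE, prob = theta[d, ])
      used_topics[[d]] <- unique(zs)
      ws <- character(lens[d])
      for (t in unique(zs)) {
        pos <- which(zs == t)
        ws[pos] <- vocab[sample.int(V, length(pos), replace = TRUE,
                                    prob = phi[t, ])]
      }
      if (has_cred[d] && spec$n_style > 0) {
        n_st <- stats::rpois(1, spec$style_mean)
        if (n_st > 0) {
          st <- sample(style_vocab, n_st, replace = TRUE)
          ws <- sample(c(ws, st))
        }
      }
      # idiosyncratic rare tokens (typos, fragments, user-specific words):
      # the heavy tail real short-text corpora always carry
      n_hapax <- stats::rpois(1, 1)
      if (n_hapax > 0) {
        ws <- sample(c(ws, sprintf("u%05dx%d", d, seq_len(n_hapax))))
      }
      texts[d] <- paste(ws, collapse = " ")
    }

    n_days <- as.numeric(spec$date_end - spec$date_start)
    offset <- stats::runif(n, 0, n_days)
    if (!is.null(spec$trend_events)) {
      for (ev in spec$trend_events) {
        onset_off <- as.numeric(as.Date(ev$onset) - spec$date_start)
        # a trend topic emits nothing before onset: every document whose
        # token draws touched it is stamped after the onset date
        sel <- vapply(used_topics, function(u) ev$topic %in% u, logical(1))
        offset[sel] <- stats::runif(sum(sel), onset_off, n_days)
      }
    }
    stamps <- as.POSIXct(spec$date_start, tz = "UTC") +
      round(offset * 86400)

    ids <- sprintf("doc%05d", seq_len(n))
    x <- corpus(
      doc_id = ids, text = texts,
      author_name = sprintf("User %05d", seq_len(n)),
      author_handle = sprintf("user%05d", seq_len(n)),
      author_bio = bios, created_at = stamps, label = "D0"
    )
    names(truth) <- ids
    lexicon <- concept_lexicon(
      phrase = clin_words,
      cui = sprintf("C%07d", seq_len(spec$n_clinical)),
      preferred_name = toupper(clin_words),
      semantic_types = "T047", normalize = FALSE
    )
    list(corpus = x, truth = truth, lexicon = lexicon, topics = phi)
  })
}

#' Precision, recall, and kept fraction of a filtered set
#'
#' Standard retrieval metrics of the "relevant" class among kept
#' documents, measured against the generator's ground-truth labels.
#'
#' @param kept Character vector of kept doc_ids (subset of the labeled
#'   ids).
#' @param truth Named label vector from [generate_corpus()].
#' @return List with `precision` (NA when nothing is kept), `recall`, and
#'   `kept_fraction`.
#' @export
truth_metrics <- function(kept, truth) {
  stopifnot(all(kept %in% names(truth)))
  n_rel <- sum(truth == "relevant")
  tp <- sum(truth[kept] == "relevant")
  list(
    precision = if (length(kept) == 0) NA_real_ else tp / length(kept),
    recall = if (n_rel == 0) NA_real_ else tp / n_rel,
    kept_fraction = length(kept) / length(truth)
  )
}

#' Write generator outputs to files
#'
#' Emits the corpus JSONL, a truth TSV (`doc_id`, `label`), and the
#' lexicon TSV under `dir`.
#'
#' @param gen Output of [generate_corpus()].
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_generated <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(gen$corpus, file.path(dir, "corpus.jsonl"))
  utils::write.table(
    data.frame(doc_id = names(gen$truth), label = unname(gen$truth)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_concept_lexicon(gen$lexicon, file.path(dir, "lexicon.tsv"))
  invisible(dir)
}
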