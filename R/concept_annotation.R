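#' Build a concept lexicon
#'
#' A concept lexicon maps normalized surface phrases (1-3 tokens,
#' lemmatized, lowercase) to clinical concepts: a concept unique identifier
#' (CUI), a preferred name, and one or more semantic-type codes. It stands
#' behind the annotator interface wherever a full Metathesaurus is
#' unavailable; precomputed annotations from an external concept tagger can
#' be loaded with [read_annotations()] instead.
#'
#' @param phrase Character vector of surface phrases.
#' @param cui Concept identifiers (recycled).
#' @param preferred_name Preferred concept names (defaults to the phrase).
#' @param semantic_types Comma-joined semantic-type codes.
#' @param normalize Normalize phrases through the same tokenizer contract
#'   as document text (default TRUE).
#' @return A `sift_lexicon` tibble with columns `phrase`, `cui`,
#'   `preferred_name`, `semantic_types`, `n_tokens`.
#' @export
concept_lexicon <- function(phrase, cui, preferred_name = phrase,
                            semantic_types = "T047", normalize = TRUE) {
  phrase <- as.character(phrase)
  if (normalize) {
    phrase <- vapply(normalize_text(phrase, query_terms = character(0),
                                    stopwords = character(0)),
                     paste, character(1), collapse = " ")
  }
  keep <- nzchar(phrase)
  out <- tibble::tibble(
    phrase = phrase[keep],
    cui = rep_len(as.character(cui), length(phrase))[keep],
    preferred_name = rep_len(as.character(preferred_name),
                             length(phrase))[keep],
    semantic_types = rep_len(as.character(semantic_types),
                             length(phrase))[keep]
  )
  out <- out[!duplicated(out$phrase), , drop = FALSE]
  out$n_tokens <- lengths(strsplit(out$phrase, " ", fixed = TRUE))
  if (any(out$n_tokens > 3)) {
    stop("lexicon phrases are limited to 3 tokens", call. = FALSE)
  }
  if (any(!nzchar(out$cui))) stop("empty CUI in lexicon", call. = FALSE)
  class(out) <- c("sift_lexicon", class(out))
  out
}

#' Bundled toy clinical ontology
#'
#' About 300 clinical surface phrases with synthetic CUIs, shipped as a
#' plain-text table for demos and tests. The identifiers are invented and
#' carry no meaning outside this package.
#'
#' @return A `sift_lexicon`.
#' @export
toy_concept_lexicon <- function() {
  path <- system.file("extdata", "toy_concepts.tsv", package = "topicsift")
  read_concept_lexicon(path)
}

#' Read / write a concept lexicon
#'
#' TSV with columns `phrase`, `cui`, `preferred_name`, `semantic_types`
#' (comma-joined).
#'
#' @param path File path.
#' @return `read_concept_lexicon()` a `sift_lexicon`;
#'   `write_concept_lexicon()` the path, invisibly.
#' @export
read_concept_lexicon <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  concept_lexicon(df$phrase, df$cui, df$preferred_name, df$semantic_types)
}

#' @rdname read_concept_lexicon
#' @param lexicon A `sift_lexicon`.
#' @export
write_concept_lexicon <- function(lexicon, path) {
  df <- as.data.frame(lexicon[c("phrase", "cui", "preferred_name",
                                "semantic_types")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Annotate tokenized documents with concept mentions
#'
#' Greedy longest-match left-to-right over each token sequence: at each
#' position the longest lexicon phrase (up to 3 tokens) anchored there is
#' emitted as one mention and the scan resumes after it, so each token
#' participates in at most one mention. Repeated occurrences yield repeated
#' mentions (multiset semantics). No negation or word-sense handling is
#' attempted; downstream relevance filtering is designed to absorb false
#' positive annotations.
#'
#' @param tokdocs Named list of token vectors (from [tokenize_corpus()]).
#' @param lexicon A `sift_lexicon`.
#' @return A tibble of mentions with columns `doc_id`, `cui`,
#'   `preferred_name`, `semantic_types`, `trigger`.
#' @export
annotate <- function(tokdocs, lexicon) {
  lex_map <- seq_len(nrow(lexicon))
  names(lex_map) <- lexicon$phrase
  max_len <- if (nrow(lexicon)) max(lexicon$n_tokens) else 1L
  rows <- list()
  for (d in seq_along(tokdocs)) {
    toks <- tokdocs[[d]]
    did <- names(tokdocs)[d]
    i <- 1L
    L <- length(toks)
    while (i <= L) {
      hit <- 0L
      for (n in seq(min(max_len, L - i + 1L), 1L)) {
        phr <- paste(toks[i:(i + n - 1L)], collapse = " ")
        j <- lex_map[phr]
        if (!is.na(j)) {
          hit <- n
          rows[[length(rows) + 1L]] <- list(
            doc_id = did, cui = lexicon$cui[j],
            preferred_name = lexicon$preferred_name[j],
            semantic_types = lexicon$semantic_types[j],
            trigger = phr
          )
          break
        }
      }
      i <- i + max(hit, 1L)
    }
  }
  if (length(rows) == 0) return(empty_mentions())
  tibble::tibble(
    doc_id = vapply(rows, `[[`, character(1), "doc_id"),
    cui = vapply(rows, `[[`, character(1), "cui"),
    preferred_name = vapply(rows, `[[`, character(1), "preferred_name"),
    semantic_types = vapply(rows, `[[`, character(1), "semantic_types"),
    trigger = vapply(rows, `[[`, character(1), "trigger")
  )
}

empty_mentions <- function() {
  tibble::tibble(doc_id = character(), cui = character(),
                 preferred_name = character(), semantic_types = character(),
                 trigger = character())
}

#' Read / write precomputed concept annotations
#'
#' A minimal fielded dialect for externally produced mentions: TSV with
#' columns `doc_id`, `cui`, `preferred_name`, `semantic_types`
#' (comma-joined), `trigger`. Triggers are normalized through the same
#' pipeline as document text on read. Mentions for unknown documents are
#' skipped with a warning; malformed lines are an error naming the line.
#'
#' @param path File path.
#' @param known_ids Optional character vector of valid `doc_id`s.
#' @return A mentions tibble as from [annotate()].
#' @export
read_annotations <- function(path, known_ids = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1) return(empty_mentions())
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  need <- c("doc_id", "cui", "preferred_name", "semantic_types", "trigger")
  if (!all(need %in% header)) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad)) {
    stop("malformed annotation line ", bad[1] + 1L, " in ", path,
         call. = FALSE)
  }
  mat <- do.call(rbind, parts)
  colnames(mat) <- header
  trig <- vapply(normalize_text(mat[, "trigger"],
                                query_terms = character(0),
                                stopwords = character(0)),
                 paste, character(1), collapse = " ")
  out <- tibble::tibble(
    doc_id = mat[, "doc_id"], cui = mat[, "cui"],
    preferred_name = mat[, "preferred_name"],
    semantic_types = mat[, "semantic_types"], trigger = trig
  )
  if (!is.null(known_ids)) {
    unknown <- !out$doc_id %in% known_ids
    if (any(unknown)) {
      warning(sum(unknown), " mention(s) reference unknown doc_ids; skipped",
              call. = FALSE)
      out <- out[!unknown, , drop = FALSE]
    }
  }
  out
}

#' @rdname read_annotations
#' @param mentions A mentions tibble.
#' @export
write_annotations <- function(mentions, path) {
  utils::write.table(as.data.frame(mentions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Pre-filter concepts by initial relevance
#'
#' Removes concept mentions whose trigger is not at least as frequent per
#' document inside the author-filtered corpus D1 as in the remainder of the
#' raw corpus D0: a mention with trigger c is retained iff
#' Rel(c; D1, D0) >= 1. Run once before the first filtering iteration; the
#' removal persists for the whole run.
#'
#' @param mentions Mentions tibble over D1 documents.
#' @param tok_d1,tok_d0 Tokenized D1 and D0 (named token lists). Trigger
#'   occurrences are counted in each with the same longest-match annotator,
#'   so multiword triggers count correctly.
#' @param lexicon The `sift_lexicon` used to annotate.
#' @param eps Relevance smoothing constant.
#' @return The retained mentions tibble, with the dropped trigger set in
#'   attribute `"removed_triggers"`.
#' @export
prefilter_concepts <- function(mentions, tok_d1, tok_d0, lexicon,
                               eps = 0.001) {
  if (!all(names(tok_d1) %in% names(tok_d0))) {
    stop("D1 must be a subset of D0 by doc_id", call. = FALSE)
  }
  m0 <- annotate(tok_d0, lexicon)
  fA <- table(mentions$trigger)
  fB <- table(m0$trigger)
  triggers <- unique(mentions$trigger)
  fB_vals <- as.numeric(fB[triggers])
  fB_vals[is.na(fB_vals)] <- 0
  rel <- term_relevance(
    triggers,
    f_A = as.numeric(fA[triggers]),
    f_B = fB_vals,
    size_A = length(tok_d1), size_B = length(tok_d0), eps = eps
  )
  keep_triggers <- triggers[rel >= 1]
  out <- mentions[mentions$trigger %in% keep_triggers, , drop = FALSE]
  attr(out, "removed_triggers") <- setdiff(triggers, keep_triggers)
  out
}
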