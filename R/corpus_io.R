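#' Construct a corpus of short documents
#'
#' A corpus is a tibble with one row per document and a `label` attribute
#' naming its position in the filtering chain (`"D0"` for the raw corpus,
#' `"D1"` after author filtering, `"D2"`, `"D3"`, ... for successive
#' relevance-filtered subsets).
#'
#' @param doc_id Character vector of unique document identifiers.
#' @param text Raw post text, preserved byte-for-byte.
#' @param author_name,author_handle,author_bio Author profile fields. The
#'   handle must be non-empty for every document; name and bio may be empty
#'   strings but are never `NA`.
#' @param created_at Post timestamps, anything `lubridate` can parse as
#'   ISO-8601; stored as POSIXct in UTC.
#' @param thread_id Optional thread key grouping consecutive posts by the
#'   same author; `NA` for standalone posts.
#' @param label Corpus label, e.g. `"D0"`.
#' @return A `sift_corpus` tibble with columns `doc_id`, `text`,
#'   `author_name`, `author_handle`, `author_bio`, `created_at`, `thread_id`.
#' @export
corpus <- function(doc_id, text,
                   author_name = "", author_handle = "user",
                   author_bio = "", created_at = "2020-01-01T00:00:00Z",
                   thread_id = NA_character_, label = "D0") {
  doc_id <- as.character(doc_id)
  if (anyDuplicated(doc_id)) {
    dup <- doc_id[duplicated(doc_id)][1L]
    stop("duplicate doc_id: '", dup, "'", call. = FALSE)
  }
  n <- length(doc_id)
  out <- tibble::tibble(
    doc_id = doc_id,
    text = rep_len(as.character(text), n),
    author_name = rep_len(as.character(author_name), n),
    author_handle = rep_len(as.character(author_handle), n),
    author_bio = rep_len(as.character(author_bio), n),
    created_at = rep_len(parse_utc(created_at), n),
    thread_id = rep_len(as.character(thread_id), n)
  )
  out$author_name[is.na(out$author_name)] <- ""
  out$author_bio[is.na(out$author_bio)] <- ""
  if (n > 0 && any(is.na(out$author_handle) | out$author_handle == "")) {
    stop("author_handle must be non-empty", call. = FALSE)
  }
  new_corpus(out, label)
}

new_corpus <- function(df, label) {
  structure(df, class = c("sift_corpus", class(tibble::tibble())),
            label = label)
}

#' @export
print.sift_corpus <- function(x, ...) {
  cat(sprintf("<sift_corpus %s: %d documents>\n", corpus_label(x), nrow(x)))
  NextMethod()
}

#' Corpus label and size
#'
#' @param x A `sift_corpus`.
#' @return `corpus_label()` the label string; `corpus_size()` the document
#'   count M.
#' @export
corpus_label <- function(x) attr(x, "label") %||% "D?"

#' @rdname corpus_label
#' @export
corpus_size <- function(x) nrow(x)

#' Relabel a corpus
#' @param x A `sift_corpus`.
#' @param label New label.
#' @return The corpus with its label replaced.
#' @export
set_corpus_label <- function(x, label) {
  attr(x, "label") <- label
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

corpus_cols <- c("doc_id", "text", "author_name", "author_handle",
                 "author_bio", "created_at", "thread_id")

parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate::with_tz(x, "UTC"))
  out <- suppressWarnings(
    lubridate::parse_date_time(
      as.character(x),
      orders = c("Ymd HMS", "Ymd HM", "Ymd", "Ymd HMSz"),
      tz = "UTC", quiet = TRUE
    )
  )
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    stop("unparseable timestamp: '", as.character(x)[bad][1L], "'",
         call. = FALSE)
  }
  out
}

#' Read a corpus from disk
#'
#' Reads the package's on-disk document format: JSON Lines (one JSON object
#' per line) or TSV, with fields `doc_id`, `text`, `author_name`,
#' `author_handle`, `author_bio`, `created_at`, `thread_id`. Only `doc_id`
#' and `text` are required per record; missing author fields default to
#' empty strings (handle to `"user"`), missing timestamps to `NA`.
#' Timestamps are normalized to UTC on read. Input order is preserved and
#' duplicate `doc_id`s are rejected.
#'
#' @param path File to read.
#' @param format `"jsonl"` or `"tsv"`; default guesses from the extension.
#' @param label Corpus label to attach.
#' @return A `sift_corpus`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "tsv"),
                        label = "D0") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "jsonl"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) NULL)
      if (is.null(rec) || is.null(rec$doc_id) || is.null(rec$text)) {
        stop("malformed record at line ", i, " of ", path, call. = FALSE)
      }
      recs[[i]] <- rec
    }
    fld <- function(name, default) {
      vapply(recs, function(r) {
        v <- r[[name]]
        if (is.null(v) || length(v) == 0 || is.na(v)) default
        else as.character(v)
      }, character(1))
    }
    if (length(recs) == 0) return(empty_corpus(label))
    corpus(
      doc_id = fld("doc_id", NA_character_),
      text = fld("text", ""),
      author_name = fld("author_name", ""),
      author_handle = fld("author_handle", "user"),
      author_bio = fld("author_bio", ""),
      created_at = fld("created_at", NA_character_),
      thread_id = fld("thread_id", NA_character_),
      label = label
    )
  } else {
    df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                            colClasses = "character", na.strings = NULL,
                            fileEncoding = "UTF-8",
                            check.names = FALSE)
    if (nrow(df) == 0) return(empty_corpus(label))
    if (!all(c("doc_id", "text") %in% names(df))) {
      stop("TSV corpus must have doc_id and text columns", call. = FALSE)
    }
    get <- function(name, default) {
      if (name %in% names(df)) {
        v <- unescape_tsv(df[[name]])
        v[v == ""] <- default
        v
      } else rep(default, nrow(df))
    }
    corpus(
      doc_id = unescape_tsv(df$doc_id),
      text = unescape_tsv(df$text),
      author_name = get("author_name", ""),
      author_handle = get("author_handle", "user"),
      author_bio = get("author_bio", ""),
      created_at = get("created_at", NA_character_),
      thread_id = get("thread_id", NA_character_),
      label = label
    )
  }
}

empty_corpus <- function(label = "D0") {
  new_corpus(tibble::tibble(
    doc_id = character(), text = character(),
    author_name = character(), author_handle = character(),
    author_bio = character(),
    created_at = as.POSIXct(character(), tz = "UTC"),
    thread_id = character()
  ), label)
}

# TSV cells cannot hold literal tabs/newlines; escape them reversibly.
escape_tsv <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_tsv <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    parts <- strsplit(x[[i]], "\\\\", fixed = TRUE)[[1]]
    if (length(parts) == 0) parts <- ""
    parts <- gsub("\\t", "\t", parts, fixed = TRUE)
    parts <- gsub("\\n", "\n", parts, fixed = TRUE)
    out[[i]] <- paste(parts, collapse = "\\")
  }
  out
}

#' Write a corpus to disk
#'
#' Inverse of [read_corpus()]: `read_corpus(write_corpus(x, p), ...)`
#' reproduces `x` field-for-field, including unicode text.
#'
#' @param x A `sift_corpus`.
#' @param path Destination file.
#' @param format `"jsonl"` or `"tsv"` (default guesses from extension).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "jsonl"
  }
  ts <- format_utc(x$created_at)
  if (format == "jsonl") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(x))) {
      rec <- list(
        doc_id = x$doc_id[i], text = x$text[i],
        author_name = x$author_name[i],
        author_handle = x$author_handle[i],
        author_bio = x$author_bio[i],
        created_at = ts[i],
        thread_id = x$thread_id[i]
      )
      rec <- rec[!vapply(rec, function(v) is.na(v), logical(1))]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
                 con, useBytes = TRUE)
    }
  } else {
    df <- data.frame(
      doc_id = escape_tsv(x$doc_id), text = escape_tsv(x$text),
      author_name = escape_tsv(x$author_name),
      author_handle = escape_tsv(x$author_handle),
      author_bio = escape_tsv(x$author_bio),
      created_at = ifelse(is.na(ts), "", ts),
      thread_id = ifelse(is.na(x$thread_id), "", escape_tsv(x$thread_id)),
      stringsAsFactors = FALSE
    )
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
    if (nrow(df) > 0) {
      rows <- do.call(paste, c(unname(df), sep = "\t"))
      writeLines(enc2utf8(rows), con, useBytes = TRUE)
    }
  }
  invisible(path)
}

format_utc <- function(x) {
  ifelse(is.na(x), NA_character_,
         format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

#' Group documents into threads
#'
#' Documents sharing a `thread_id` form one group, ordered by `created_at`;
#' documents without a thread form singleton groups keyed by their own
#' `doc_id`. The groups partition the corpus exactly.
#'
#' @param x A `sift_corpus`.
#' @return Named list of character vectors of `doc_id`s.
#' @export
group_threads <- function(x) {
  key <- ifelse(is.na(x$thread_id), x$doc_id, x$thread_id)
  ord <- order(match(key, unique(key)), x$created_at)
  split(x$doc_id[ord], factor(key[ord], levels = unique(key[ord])))
}

#' Subset a corpus by document id
#'
#' @param x A `sift_corpus`.
#' @param ids Character vector of `doc_id`s to keep; original corpus order
#'   is preserved.
#' @param label Label for the subset (default keeps the old one).
#' @return A `sift_corpus`.
#' @export
corpus_subset <- function(x, ids, label = corpus_label(x)) {
  new_corpus(x[x$doc_id %in% ids, , drop = FALSE], label)
}
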