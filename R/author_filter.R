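#' Default healthcare-professional credential lexicon
#'
#' A heuristic list of 27 credential keywords spanning medical titles
#' ("MD", "Dr"), professions ("physician", "nurse"), and prefix-wildcard
#' specialties ("epidemiolog*", "cardiolog*"). The list is a reproducible
#' default, not an authoritative registry of credentials: real deployments
#' should review and adapt it to their platform and language. Short
#' all-caps entries match case-sensitively at token boundaries so that
#' e.g. "MD" does not fire inside unrelated words.
#'
#' @return Character vector of 27 patterns usable as `lexicon` in
#'   [is_hcp()] and [filter_hcp()]. Entries ending in `*` are prefix
#'   wildcards.
#' @export
hcp_lexicon <- function() {
  c("MD", "DO", "RN", "NP", "PA", "Dr",
    "physician", "surgeon", "nurse", "pharmacist", "paramedic",
    "intensivist", "hospitalist", "resident physician", "medical student",
    "infectious disease", "public health",
    "cardiolog*", "epidemiolog*", "virolog*", "immunolog*", "pediatric*",
    "anesthesi*", "radiolog*", "patholog*", "oncolog*", "psychiat*")
}

validate_lexicon <- function(lexicon) {
  if (length(lexicon) == 0) stop("credential lexicon is empty", call. = FALSE)
  bad <- grepl("\\*", sub("\\*$", "", lexicon))
  if (any(bad)) {
    stop("wildcard '*' must be terminal: '", lexicon[bad][1L], "'",
         call. = FALSE)
  }
  invisible(lexicon)
}

# One credential pattern against one profile field.
# Matching rules:
#   * "x*"          -> any token with case-insensitive prefix x
#   * <=3 chars     -> case-sensitive whole-token match (credentials: "MD")
#   * longer        -> case-insensitive match starting at a word boundary
match_pattern <- function(pattern, field) {
  if (grepl("\\*$", pattern)) {
    stem <- sub("\\*$", "", pattern)
    grepl(paste0("\\b", escape_regex(stem)), field,
          ignore.case = TRUE, perl = TRUE)
  } else if (nchar(pattern) <= 3) {
    grepl(paste0("(?<![A-Za-z0-9])", escape_regex(pattern),
                 "(?![A-Za-z0-9])"),
          field, perl = TRUE)
  } else {
    grepl(paste0("\\b", escape_regex(pattern)), field,
          ignore.case = TRUE, perl = TRUE)
  }
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Does an author self-identify as a healthcare professional?
#'
#' Scans the display name, handle (leading "@" stripped), and bio for any
#' credential pattern. Vectorized over authors.
#'
#' @param author_name,author_handle,author_bio Profile fields (character
#'   vectors, recycled to a common length).
#' @param lexicon Credential patterns; see [hcp_lexicon()].
#' @return Logical vector.
#' @export
is_hcp <- function(author_name, author_handle, author_bio,
                   lexicon = hcp_lexicon()) {
  validate_lexicon(lexicon)
  n <- max(length(author_name), length(author_handle), length(author_bio))
  name <- rep_len(as.character(author_name), n)
  handle <- sub("^@", "", rep_len(as.character(author_handle), n))
  bio <- rep_len(as.character(author_bio), n)
  hit <- rep(FALSE, n)
  for (p in lexicon) {
    hit <- hit | match_pattern(p, name) | match_pattern(p, handle) |
      match_pattern(p, bio)
  }
  hit
}

#' Filter a corpus to healthcare-professional authors
#'
#' Produces the D1 corpus from D0: keeps exactly the documents whose author
#' passes [is_hcp()], preserving order. This heuristic is deliberately
#' sensitive rather than precise — credentialed authors posting irrelevant
#' content pass it, and the iterative relevance filter downstream is what
#' removes them.
#'
#' @param x A `sift_corpus`.
#' @param lexicon Credential patterns; see [hcp_lexicon()].
#' @param label Label for the filtered corpus (default `"D1"`).
#' @return A `sift_corpus` containing the HCP-authored subset.
#' @export
filter_hcp <- function(x, lexicon = hcp_lexicon(), label = "D1") {
  keep <- is_hcp(x$author_name, x$author_handle, x$author_bio, lexicon)
  new_corpus(x[keep, , drop = FALSE], label)
}

#' Read a credential lexicon file
#'
#' One pattern per line; blank lines and lines starting with `#` ignored.
#'
#' @param path File path.
#' @return Character vector of patterns.
#' @export
read_hcp_lexicon <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  validate_lexicon(lines)
  lines
}
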