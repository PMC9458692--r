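#' Retrieve index entries for a normalized key
#'
#' Exact-key retrieval, falling back to prefix retrieval on the last word of
#' the key when the exact key has no hits (so `"brca"` finds entries keyed
#' `"brca1"` and `"brca2"`). Every returned entry's `lookup_key` starts with
#' the queried words.
#'
#' @param index A `kg_index` tibble.
#' @param key Normalized (stemmed, space-separated) key string.
#' @return Tibble of matching index entries (possibly empty).
#' @export
lookup_entries <- function(index, key) {
  hits <- index[index$lookup_key == key, , drop = FALSE]
  if (nrow(hits) > 0) {
    return(tibble::as_tibble(hits))
  }
  # prefix extension: same word count, last word extended
  words <- strsplit(key, " ", fixed = TRUE)[[1]]
  n <- length(words)
  cand <- index[startsWith(index$lookup_key, key), , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::as_tibble(cand))
  }
  keep <- vapply(cand$lookup_key, function(k) {
    kw <- strsplit(k, " ", fixed = TRUE)[[1]]
    length(kw) == n && startsWith(kw[n], words[n])
  }, TRUE, USE.NAMES = FALSE)
  tibble::as_tibble(cand[keep, , drop = FALSE])
}

#' Segment a question into index-backed tokens
#'
#' Normalizes the question exactly like index keys (lowercase, stopword
#' removal, Porter stemming), then scans left to right taking at each
#' position the longest word sequence that has index hits; unmatched words
#' are skipped. Tokens never overlap.
#'
#' @param index A `kg_index` tibble.
#' @param question Question text.
#' @param stopwords Stopword list (must match the lookup configuration).
#' @param max_token_words Longest key length tried (defaults to the longest
#'   key in the index).
#' @return A tibble with one row per token: `token` (normalized words),
#'   `n_words`, and `entries` (list column of index-entry tibbles). The
#'   character vector of skipped words is in attribute `unmatched`; an empty
#'   tibble with that attribute is the typed "no-match" outcome.
#' @export
tokenize_question <- function(index, question, stopwords = default_stopwords(),
                              max_token_words = NULL) {
  if (nrow(index) == 0) stop("tokenize_question(): empty index", call. = FALSE)
  words <- normalize_words(question, stopwords = stopwords)[[1]]
  if (is.null(max_token_words)) {
    max_token_words <- max(1L, lengths(strsplit(index$lookup_key, " ", fixed = TRUE)))
    max_token_words <- max(max_token_words)
  }
  tokens <- list()
  unmatched <- character(0)
  i <- 1L
  n <- length(words)
  while (i <= n) {
    found <- FALSE
    for (len in seq(min(max_token_words, n - i + 1L), 1L)) {
      key <- paste(words[i:(i + len - 1L)], collapse = " ")
      entries <- lookup_entries(index, key)
      if (nrow(entries) > 0) {
        tokens[[length(tokens) + 1L]] <- list(token = key, n_words = len, entries = entries)
        i <- i + len
        found <- TRUE
        break
      }
    }
    if (!found) {
      unmatched <- c(unmatched, words[i])
      i <- i + 1L
    }
  }
  out <- tibble::tibble(
    token = vapply(tokens, `[[`, "", "token"),
    n_words = vapply(tokens, `[[`, 0L, "n_words"),
    entries = lapply(tokens, `[[`, "entries")
  )
  attr(out, "unmatched") <- unmatched
  out
}
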