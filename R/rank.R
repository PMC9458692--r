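#' Group equivalent index hits of one token
#'
#' Entries retrieved for a token are grouped by `(class_iri, property_iri)`:
#' instances of one class matched through one property form a single
#' candidate (so genes labelled "BRCA1" and "BRCA2" collapse into one
#' candidate with two members). Group PageRank is the maximum over members;
#' string similarity is the best normalized Levenshtein ratio between the
#' token and a member's lookup key.
#'
#' @param entries Tibble of index entries (from [lookup_entries()]).
#' @param token Normalized token string the entries were retrieved for.
#' @return Tibble of candidate matches: `token`, `kind`
#'   (`"class"`/`"property"`/`"instance"`), `class_iri`, `property_iri`,
#'   `members` (list of member URIs), `n_members`, `matched_key`,
#'   `string_sim`, `pagerank`.
#' @export
group_candidates <- function(entries, token) {
  if (nrow(entries) == 0) {
    return(tibble::tibble(
      token = character(0), kind = character(0), class_iri = character(0),
      property_iri = character(0), node_iri = character(0), members = list(),
      n_members = integer(0), matched_key = character(0),
      string_sim = numeric(0), pagerank = numeric(0)
    ))
  }
  entries$.sim <- string_similarity(token, entries$lookup_key)
  # schema anchor: instances attach via their class; a metadata entry *is*
  # its own anchor (the class node, or the property's schema edges)
  entries$.node <- ifelse(
    entries$class_iri %in% c(OWL_CLASS, RDF_PROPERTY),
    entries$uri, entries$class_iri
  )
  # one candidate per metadata resource regardless of which key variant hit
  # (label vs URI fragment); instance hits stay split by matched property
  entries$.prop_group <- ifelse(
    entries$class_iri %in% c(OWL_CLASS, RDF_PROPERTY), "", entries$property_iri
  )
  entries |>
    dplyr::group_by(
      .data$class_iri, .data$.prop_group,
      node_iri = .data$.node
    ) |>
    dplyr::summarise(
      property_iri = min(.data$property_iri),
      members = list(sort(unique(.data$uri))),
      n_members = length(unique(.data$uri)),
      matched_key = .data$lookup_key[which.max(.data$.sim)],
      string_sim = max(.data$.sim),
      pagerank = max(.data$pagerank),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      token = token,
      kind = dplyr::case_when(
        .data$class_iri == OWL_CLASS ~ "class",
        .data$class_iri == RDF_PROPERTY ~ "property",
        TRUE ~ "instance"
      )
    ) |>
    dplyr::select(
      "token", "kind", "class_iri", "property_iri", "node_iri", "members",
      "n_members", "matched_key", "string_sim", "pagerank"
    )
}

#' Normalized Levenshtein similarity
#'
#' `1 - distance / max(length)`, in `[0, 1]`.
#'
#' @param a Single string.
#' @param b Character vector.
#' @return Numeric vector of similarities.
#' @export
string_similarity <- function(a, b) {
  d <- as.numeric(utils::adist(a, b))
  1 - d / pmax(nchar(a), nchar(b))
}

#' Score, filter and rank candidate matches of one token
#'
#' Candidates are gated by semantic similarity (word-embedding cosine between
#' the token and the matched key; out-of-vocabulary words pass by default),
#' then scored and ordered. The score is
#' `round(string_sim, 2) + pagerank / max_pagerank` when node centrality is
#' enabled, and plain `round(string_sim, 2)` in the string-similarity-only
#' ablation mode. Remaining ties break deterministically on
#' `(class_iri, property_iri)`. At most `top_n` candidates survive, bounding
#' the downstream combination count by `top_n ^ n_tokens`.
#'
#' @param matches Candidate tibble from [group_candidates()].
#' @param embeddings Optional [read_word_vectors()] provider.
#' @param semantic_threshold Cosine below which a candidate is discarded.
#' @param top_n Maximum candidates kept per token.
#' @param use_pagerank `FALSE` selects the ablation (string-only) ranking.
#' @param max_pagerank Normalization constant, usually the largest PageRank
#'   in the index; defaults to the largest among `matches`.
#' @return The top candidates with `semantic_sim`, `score` and `rank`
#'   columns, ordered by rank.
#' @export
score_candidates <- function(matches, embeddings = NULL, semantic_threshold = 0.3,
                             top_n = 3L, use_pagerank = TRUE, max_pagerank = NULL) {
  stopifnot(top_n >= 1)
  if (nrow(matches) == 0) {
    matches$semantic_sim <- numeric(0)
    matches$score <- numeric(0)
    matches$rank <- integer(0)
    return(matches)
  }
  matches$semantic_sim <- vapply(
    matches$matched_key,
    function(k) embedding_similarity(matches$token[1], k, embeddings),
    0, USE.NAMES = FALSE
  )
  keep <- is.na(matches$semantic_sim) | matches$semantic_sim >= semantic_threshold
  matches <- matches[keep, , drop = FALSE]
  if (nrow(matches) == 0) {
    matches$score <- numeric(0)
    matches$rank <- integer(0)
    return(matches) # token becomes unconstrained
  }
  if (is.null(max_pagerank)) max_pagerank <- max(matches$pagerank, 1e-12)
  max_pagerank <- max(max_pagerank, 1e-12)
  matches$score <- round(matches$string_sim, 2) +
    if (use_pagerank) matches$pagerank / max_pagerank else 0
  matches <- dplyr::arrange(
    matches, dplyr::desc(.data$score), .data$class_iri, .data$property_iri
  )
  matches <- utils::head(matches, top_n)
  matches$rank <- seq_len(nrow(matches))
  matches
}

#' Read word vectors in word2vec text format
#'
#' First line `"<n> <dim>"`, then one word and its components per line.
#'
#' @param path Vector file path.
#' @return An embedding provider: list with `vectors` (matrix, words as row
#'   names), class `kg_embeddings`.
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  header <- as.integer(strsplit(trimws(lines[1]), " +")[[1]])
  body <- strsplit(trimws(lines[-1]), " +")
  words <- vapply(body, `[[`, "", 1L)
  mat <- t(vapply(
    body, function(x) as.numeric(x[-1]),
    numeric(header[2])
  ))
  rownames(mat) <- words
  structure(list(vectors = mat), class = "kg_embeddings")
}

#' Cosine similarity of two phrases under a word-vector provider
#'
#' Each phrase is represented by the mean of its in-vocabulary word vectors.
#' Returns `NA` when either side is fully out of vocabulary (such matches
#' pass the semantic gate by default).
#'
#' @param a,b Space-separated phrases.
#' @param embeddings A `kg_embeddings` provider, or `NULL` (always `NA`).
#' @return Cosine in `[-1, 1]`, or `NA`.
#' @export
embedding_similarity <- function(a, b, embeddings = NULL) {
  if (is.null(embeddings)) {
    return(NA_real_)
  }
  vec <- function(phrase) {
    words <- strsplit(phrase, " ", fixed = TRUE)[[1]]
    words <- words[words %in% rownames(embeddings$vectors)]
    if (length(words) == 0) {
      return(NULL)
    }
    colMeans(embeddings$vectors[words, , drop = FALSE])
  }
  va <- vec(a)
  vb <- vec(b)
  if (is.null(va) || is.null(vb)) {
    return(NA_real_)
  }
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}
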