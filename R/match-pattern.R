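#' Build a basic graph pattern
#'
#' Convenience constructor for the triple-pattern tables consumed by
#' [match_pattern()]. Each argument is a character vector of length 3
#' (subject, predicate, object). Fields beginning with `?` are variables.
#' Constant subjects and predicates are absolute IRIs; constant objects are
#' IRIs, or literals written in N-Triples form (starting with `"`).
#'
#' @param ... Length-3 character vectors, one per triple pattern.
#' @return A tibble with columns `subject`, `predicate`, `object`.
#' @export
bgp <- function(...) {
  pats <- list(...)
  stopifnot(all(vapply(pats, length, 0L) == 3L))
  tibble::tibble(
    subject = vapply(pats, `[[`, "", 1L),
    predicate = vapply(pats, `[[`, "", 2L),
    object = vapply(pats, `[[`, "", 3L)
  )
}

is_var <- function(x) startsWith(x, "?")

# Value representation in binding tables: bare IRI strings for IRI terms,
# N-Triples term strings (starting with a double quote) for literals. The two
# cannot collide because IRIs never start with '"'.
binding_value <- function(object, object_kind, datatype, lang) {
  as.character(
    ifelse(object_kind == "iri", object, object_term(object, object_kind, datatype, lang))
  )
}

#' Evaluate a basic graph pattern over a knowledge graph
#'
#' A naive nested-loop join over the triple set: patterns are applied left to
#' right, each extending the current set of variable bindings. The result is
#' exactly the set of rows an exhaustive join produces, deduplicated and in a
#' deterministic (sorted) order.
#'
#' @param graph A [kg()] object.
#' @param patterns A pattern table from [bgp()] (or any data frame with
#'   `subject`, `predicate`, `object` character columns).
#' @return A tibble with one column per variable (names without the `?`).
#'   IRI bindings are bare IRI strings; literal bindings are N-Triples term
#'   strings (see [bgp()]).
#' @export
match_pattern <- function(graph, patterns) {
  patterns <- tibble::as_tibble(patterns)
  if (nrow(patterns) == 0) stop("match_pattern(): empty pattern", call. = FALSE)
  bad <- !vapply(patterns, is.character, TRUE)
  if (any(bad) || anyNA(patterns) || any(patterns == "")) {
    stop("match_pattern(): pattern fields must be non-empty strings", call. = FALSE)
  }
  bindings <- tibble::tibble(.rows = 1L)
  for (i in seq_len(nrow(patterns))) {
    cand <- pattern_candidates(graph, patterns[i, ])
    if (ncol(cand) == 0) { # all-constant pattern: pure existence check
      if (nrow(cand) == 0) bindings <- bindings[0, , drop = FALSE]
      next
    }
    shared <- intersect(names(bindings), names(cand))
    bindings <- if (length(shared) > 0) {
      dplyr::inner_join(bindings, cand, by = shared, relationship = "many-to-many")
    } else if (ncol(bindings) == 0) {
      cand
    } else {
      dplyr::cross_join(bindings, cand)
    }
    if (nrow(bindings) == 0) break
  }
  vars <- unique(unlist(patterns))
  vars <- sub("^\\?", "", vars[is_var(vars)])
  for (v in setdiff(vars, names(bindings))) bindings[[v]] <- character(0)
  bindings <- dplyr::distinct(bindings[, vars, drop = FALSE])
  dplyr::arrange(bindings, dplyr::across(dplyr::everything()))
}

# Rows of the graph compatible with one triple pattern, projected onto the
# pattern's variables.
pattern_candidates <- function(graph, pat) {
  rows <- graph
  if (!is_var(pat$subject)) rows <- rows[rows$subject == pat$subject, ]
  if (!is_var(pat$predicate)) rows <- rows[rows$predicate == pat$predicate, ]
  if (!is_var(pat$object)) {
    if (startsWith(pat$object, "\"")) {
      key <- object_term(rows$object, rows$object_kind, rows$datatype, rows$lang)
      rows <- rows[rows$object_kind == "literal" & key == pat$object, ]
    } else {
      rows <- rows[rows$object_kind == "iri" & rows$object == pat$object, ]
    }
  }
  position_values <- list(
    subject = rows$subject,
    predicate = rows$predicate,
    object = binding_value(rows$object, rows$object_kind, rows$datatype, rows$lang)
  )
  cols <- list()
  keep <- rep(TRUE, nrow(rows))
  for (pos in names(position_values)) {
    f <- pat[[pos]]
    if (!is_var(f)) next
    v <- sub("^\\?", "", f)
    if (v %in% names(cols)) {
      keep <- keep & cols[[v]] == position_values[[pos]] # repeated variable
    } else {
      cols[[v]] <- position_values[[pos]]
    }
  }
  out <- tibble::as_tibble(cols)
  if (length(cols) > 0) out <- out[keep, , drop = FALSE] else out <- tibble::tibble(.rows = sum(keep))
  dplyr::distinct(out)
}
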