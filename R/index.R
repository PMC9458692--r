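#' Indexing configuration
#'
#' Controls which literal properties are searchable, whether URI fragments
#' are parsed into keywords, and how keys are generated.
#'
#' @param indexed_properties IRIs of literal properties to index; empty means
#'   every string literal (the default behaviour).
#' @param index_uri_fragments Also index keywords split out of URI local
#'   names (instances, classes and properties)?
#' @param max_ngram_len Longest word n-gram stored as a lookup key.
#' @param verbose_word_cap Literals longer than this many words are indexed
#'   only by their first sentence (verbose fields should not be indexed in
#'   their entirety).
#' @param stopwords Stopword list; stripped from *questions* at lookup time
#'   only, never from index keys.
#' @param splitters Punctuation characters treated as separators when
#'   splitting URI fragments.
#' @return A list of class `kg_index_config`.
#' @export
index_config <- function(indexed_properties = character(0),
                         index_uri_fragments = TRUE,
                         max_ngram_len = 4L,
                         verbose_word_cap = 30L,
                         stopwords = default_stopwords(),
                         splitters = c("_", "-", ".", ":", "/", ",", ";")) {
  stopifnot(max_ngram_len >= 1, verbose_word_cap >= 1)
  structure(
    list(
      indexed_properties = indexed_properties,
      index_uri_fragments = index_uri_fragments,
      max_ngram_len = as.integer(max_ngram_len),
      verbose_word_cap = as.integer(verbose_word_cap),
      stopwords = stopwords,
      splitters = splitters
    ),
    class = "kg_index_config"
  )
}

#' Build the inverted index of a knowledge graph
#'
#' Produces one row per (normalized keyword n-gram, resource) pair in the
#' layout `lookup_key | uri | class_iri | property_iri | pagerank`:
#'
#' * instance entries from indexed literal values (and, optionally, instance
#'   URI fragments, marked with the `uri_match` sentinel property);
#' * metadata entries for every ontology class (`class_iri = owl:Class`) and
#'   every property (`class_iri = rdf:Property`), keyed by their labels and
#'   split URI fragments.
#'
#' Lookup keys are lowercased, punctuation/camel-case split, Porter-stemmed
#' word n-grams. The same lookup key may map to many entries. Instances
#' without an `rdf:type` cannot be attached to the schema graph and are
#' skipped with a warning.
#'
#' @param graph A [kg()] object.
#' @param config An [index_config()].
#' @param scores Optional precomputed [pagerank_scores()] for `graph`.
#' @return A `kg_index` tibble, canonically sorted (rebuilds are
#'   byte-identical).
#' @export
build_index <- function(graph, config = index_config(), scores = NULL) {
  stopifnot(inherits(config, "kg_index_config"))
  if (is.null(scores) && nrow(graph) > 0) scores <- pagerank_scores(graph)
  pr <- function(uri) {
    if (is.null(scores)) {
      return(rep(0, length(uri)))
    }
    s <- scores$pagerank[match(uri, scores$uri)]
    ifelse(is.na(s), 0, s)
  }
  types <- kg_types(graph)
  class_iris <- sort(unique(types$class_iri))
  properties <- sort(unique(graph$predicate[graph$predicate != RDF_TYPE]))
  rows <- list()
  add <- function(keys, uri, class_iri, property_iri) {
    keys <- keys[nzchar(keys)]
    if (length(keys) == 0) {
      return(invisible())
    }
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      lookup_key = keys, uri = uri, class_iri = class_iri,
      property_iri = property_iri
    )
  }

  lits <- graph[graph$object_kind == "literal", , drop = FALSE]
  lits <- lits[is.na(lits$datatype) | lits$datatype == XSD_STRING, , drop = FALSE]
  if (length(config$indexed_properties) > 0) {
    lits <- lits[lits$predicate %in% config$indexed_properties, , drop = FALSE]
  }
  lits <- lits[!lits$subject %in% class_iris, , drop = FALSE] # class labels are metadata
  if (nrow(lits) > 0) {
    lit_types <- match(lits$subject, types$uri)
    untyped <- unique(lits$subject[is.na(lit_types)])
    if (length(untyped) > 0) {
      warning(
        "build_index(): skipping ", length(untyped),
        " untyped instance(s): ", paste(utils::head(untyped, 3), collapse = ", "),
        if (length(untyped) > 3) ", ..." else ""
      )
    }
    lits <- lits[!lits$subject %in% untyped, , drop = FALSE]
    for (i in seq_len(nrow(lits))) {
      keys <- literal_keys(lits$object[i], config)
      for (cls in types$class_iri[types$uri == lits$subject[i]]) {
        add(keys, lits$subject[i], cls, lits$predicate[i])
      }
    }
  }

  if (config$index_uri_fragments) {
    inst <- unique(types$uri[!types$uri %in% class_iris])
    for (u in inst) {
      keys <- fragment_keys(u, config)
      for (cls in types$class_iri[types$uri == u]) {
        add(keys, u, cls, URI_MATCH)
      }
    }
    for (cls in class_iris) {
      add(fragment_keys(cls, config), cls, OWL_CLASS, URI_MATCH)
    }
    for (p in properties) {
      add(fragment_keys(p, config), p, RDF_PROPERTY, URI_MATCH)
    }
  }

  # metadata label entries (class nodes with rdfs:label)
  meta_labels <- graph[
    graph$predicate == RDFS_LABEL & graph$object_kind == "literal" &
      graph$subject %in% c(class_iris, properties), ,
    drop = FALSE
  ]
  for (i in seq_len(nrow(meta_labels))) {
    is_class <- meta_labels$subject[i] %in% class_iris
    add(
      literal_keys(meta_labels$object[i], config),
      meta_labels$subject[i],
      if (is_class) OWL_CLASS else RDF_PROPERTY,
      RDFS_LABEL
    )
  }

  entries <- if (length(rows) == 0) {
    tibble::tibble(
      lookup_key = character(0), uri = character(0),
      class_iri = character(0), property_iri = character(0)
    )
  } else {
    dplyr::bind_rows(rows)
  }
  entries$pagerank <- pr(entries$uri)
  entries <- entries |>
    dplyr::distinct() |>
    dplyr::arrange(
      .data$lookup_key, .data$uri, .data$class_iri, .data$property_iri
    )
  structure(entries, class = c("kg_index", class(tibble::tibble())))
}

# N-gram keys of one literal value; long values fall back to their first
# sentence, then to the word cap.
literal_keys <- function(value, config) {
  words <- normalize_words(value)[[1]]
  if (length(words) > config$verbose_word_cap) {
    first_sentence <- strsplit(value, "[.!?]")[[1]][1]
    words <- normalize_words(first_sentence)[[1]]
    words <- utils::head(words, config$verbose_word_cap)
  }
  word_ngrams(words, config$max_ngram_len)
}

fragment_keys <- function(iri, config) {
  frag <- split_fragment(iri_local_name(iri), config$splitters)
  words <- normalize_words(frag)[[1]]
  word_ngrams(words, config$max_ngram_len)
}

#' Persist an inverted index to a single TSV file
#'
#' The file is sorted canonically so that rebuilding the same graph with the
#' same configuration writes byte-identical bytes.
#'
#' @param index A `kg_index` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  utils::write.table(
    as.data.frame(index)[, c("lookup_key", "uri", "class_iri", "property_iri", "pagerank")],
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read a persisted inverted index
#'
#' @param path File written by [write_index()].
#' @return A `kg_index` tibble.
#' @export
read_index <- function(path) {
  df <- utils::read.table(
    path,
    sep = "\t", header = TRUE, quote = "", comment.char = "",
    colClasses = c(rep("character", 4), "numeric"), fileEncoding = "UTF-8"
  )
  structure(tibble::as_tibble(df), class = c("kg_index", class(tibble::tibble())))
}

#' Append entries for new triples to an existing index
#'
#' Incremental update: existing entries are never removed, new entries are
#' unioned in and the canonical order restored.
#'
#' @param index Existing `kg_index`.
#' @param graph A [kg()] holding the appended triples (with types for any new
#'   instances).
#' @param config The [index_config()] used for the original build.
#' @param scores Optional [pagerank_scores()]; defaults to scores carried by
#'   the existing entries for known resources and 0 for new ones.
#' @return The updated `kg_index`.
#' @export
append_index <- function(index, graph, config = index_config(), scores = NULL) {
  extra <- build_index(graph, config, scores = scores)
  out <- dplyr::bind_rows(index, extra) |>
    dplyr::distinct(
      .data$lookup_key, .data$uri, .data$class_iri, .data$property_iri,
      .keep_all = TRUE
    ) |>
    dplyr::arrange(.data$lookup_key, .data$uri, .data$class_iri, .data$property_iri)
  structure(out, class = c("kg_index", class(tibble::tibble())))
}
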