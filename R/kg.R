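#' Construct a knowledge graph from a triple table
#'
#' A knowledge graph is a tibble of RDF triples with set semantics: one row
#' per distinct triple, columns `subject`, `predicate`, `object`,
#' `object_kind` (`"iri"` or `"literal"`), `datatype` and `lang`. Subjects and
#' predicates are absolute IRIs (blank nodes are skolemized at parse time).
#'
#' @param triples Data frame with at least `subject`, `predicate`, `object`
#'   columns; `object_kind`, `datatype`, `lang` are filled in if missing
#'   (objects default to IRIs).
#' @param prefixes Named character vector mapping prefix labels to namespace
#'   IRIs, kept for serialization.
#' @return A `kg` tibble (deduplicated, canonically ordered).
#' @export
kg <- function(triples = NULL, prefixes = character(0)) {
  if (is.null(triples)) {
    triples <- tibble::tibble(
      subject = character(0), predicate = character(0),
      object = character(0), object_kind = character(0),
      datatype = character(0), lang = character(0)
    )
  }
  triples <- tibble::as_tibble(triples)
  if (!"object_kind" %in% names(triples)) triples$object_kind <- "iri"
  if (!"datatype" %in% names(triples)) triples$datatype <- NA_character_
  if (!"lang" %in% names(triples)) triples$lang <- NA_character_
  triples <- triples[, c("subject", "predicate", "object", "object_kind", "datatype", "lang")]
  stopifnot(all(triples$object_kind %in% c("iri", "literal")))
  triples <- dplyr::distinct(triples)
  triples <- dplyr::arrange(
    triples, .data$subject, .data$predicate, .data$object_kind,
    .data$object, .data$datatype, .data$lang
  )
  structure(triples,
    prefixes = prefixes,
    class = c("kg", class(tibble::tibble()))
  )
}

#' @export
print.kg <- function(x, ...) {
  cat("# A knowledge graph: ", nrow(x), " triples, ",
    length(unique(x$subject)), " subjects\n",
    sep = ""
  )
  NextMethod()
}

kg_prefixes <- function(x) attr(x, "prefixes") %||% character(0)

#' Read RDF files into a knowledge graph
#'
#' Parses one or more RDF files (Turtle, N-Triples or RDF/XML), unions their
#' triples under set semantics and merges their prefix declarations. Blank
#' nodes are skolemized into stable IRIs derived from the file name and the
#' blank-node label so that downstream indexing treats them like any other
#' resource.
#'
#' @param paths Character vector of file paths.
#' @param format One of `"auto"`, `"turtle"`, `"ntriples"`, `"rdfxml"`.
#'   `"auto"` sniffs from the file extension (.ttl, .nt, .rdf/.owl/.xml).
#' @return A [kg()] tibble.
#' @export
read_kg <- function(paths, format = c("auto", "turtle", "ntriples", "rdfxml")) {
  format <- match.arg(format)
  if (length(paths) == 0) stop("read_kg(): empty input file list", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("read_kg(): file not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  parts <- lapply(paths, function(p) {
    fmt <- if (format == "auto") sniff_rdf_format(p) else format
    switch(fmt,
      turtle = parse_turtle_file(p),
      ntriples = parse_turtle_file(p), # N-Triples is a Turtle subset
      rdfxml = parse_rdfxml_file(p),
      stop("read_kg(): cannot determine RDF format of ", p, call. = FALSE)
    )
  })
  triples <- dplyr::bind_rows(lapply(parts, function(p) p$triples))
  prefixes <- unlist(lapply(parts, function(p) as.list(p$prefixes)))
  prefixes <- unlist(prefixes[!duplicated(names(prefixes))])
  kg(triples, prefixes = prefixes %||% character(0))
}

sniff_rdf_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ttl = "turtle", turtle = "turtle",
    nt = "ntriples", ntriples = "ntriples",
    rdf = "rdfxml", owl = "rdfxml", xml = "rdfxml",
    "turtle"
  )
}

#' Serialize a knowledge graph to canonical N-Triples
#'
#' Triples are emitted sorted, one per line, so that equal graphs produce
#' byte-identical files (used for fixture goldens and round-trip checks).
#'
#' @param x A [kg()] object.
#' @param path Output file path; if `NULL` the lines are returned invisibly.
#' @return The character vector of N-Triples lines, invisibly.
#' @export
write_ntriples <- function(x, path = NULL) {
  lines <- character(0)
  if (nrow(x) > 0) {
    obj <- object_term(x$object, x$object_kind, x$datatype, x$lang)
    lines <- sort(paste0("<", x$subject, "> <", x$predicate, "> ", obj, " ."))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# dplyr verbs preserve subclasses; drop "kg" before deriving plain tables
strip_kg <- function(x) {
  class(x) <- setdiff(class(x), "kg")
  x
}

#' Classes declared by rdf:type assertions
#'
#' @param x A [kg()] object.
#' @return Tibble with `class_iri` and instance counts, ordered by class IRI.
#' @export
kg_classes <- function(x) {
  strip_kg(x) |>
    dplyr::filter(.data$predicate == RDF_TYPE, .data$object_kind == "iri") |>
    dplyr::count(class_iri = .data$object, name = "n_instances") |>
    dplyr::arrange(.data$class_iri)
}

# rdf:type map: one row per (instance, class).
kg_types <- function(x) {
  strip_kg(x) |>
    dplyr::filter(.data$predicate == RDF_TYPE, .data$object_kind == "iri") |>
    dplyr::distinct(uri = .data$subject, class_iri = .data$object)
}
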