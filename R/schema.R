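#' Extract the class-level schema multigraph from instance data
#'
#' Derives property domains and ranges from the classes of the instances they
#' connect: every triple `(s, p, o)` with an IRI object contributes one edge
#' `(type(s), p, type(o))` for every type pair, and every literal-valued
#' triple contributes an edge from `type(s)` to the literal's datatype. This
#' compensates for missing or ill-defined `rdfs:domain`/`rdfs:range`
#' declarations and yields a multigraph: two classes may be connected by
#' several (possibly disjoint or inverse) properties.
#'
#' @param graph A [kg()] object whose instances carry `rdf:type`.
#' @return A `kg_schema` object: list with `nodes` (tibble `class_iri`,
#'   `label`) and `edges` (tibble `domain`, `property`, `range`,
#'   `range_kind` = `"class"` or `"datatype"`, `n_instances` witness count).
#' @export
extract_schema <- function(graph) {
  types <- kg_types(graph)
  graph <- strip_kg(graph)
  attr(graph, "prefixes") <- NULL
  if (nrow(types) == 0) {
    warning("extract_schema(): no typed instances; schema is empty")
    return(new_schema(
      tibble::tibble(class_iri = character(0), label = character(0)),
      tibble::tibble(
        domain = character(0), property = character(0), range = character(0),
        range_kind = character(0), n_instances = integer(0)
      )
    ))
  }
  body <- graph[graph$predicate != RDF_TYPE, , drop = FALSE]
  obj_edges <- body |>
    dplyr::filter(.data$object_kind == "iri") |>
    dplyr::inner_join(types, by = c(subject = "uri")) |>
    dplyr::rename(domain = "class_iri") |>
    dplyr::inner_join(types, by = c(object = "uri"), relationship = "many-to-many") |>
    dplyr::count(
      domain = .data$domain, property = .data$predicate,
      range = .data$class_iri, name = "n_instances"
    ) |>
    dplyr::mutate(range_kind = "class")
  lit_edges <- body |>
    dplyr::filter(.data$object_kind == "literal") |>
    dplyr::inner_join(types, by = c(subject = "uri")) |>
    dplyr::count(
      domain = .data$class_iri, property = .data$predicate,
      range = dplyr::coalesce(.data$datatype, XSD_STRING), name = "n_instances"
    ) |>
    dplyr::mutate(range_kind = "datatype")
  edges <- dplyr::bind_rows(obj_edges, lit_edges) |>
    dplyr::select("domain", "property", "range", "range_kind", "n_instances") |>
    dplyr::arrange(.data$domain, .data$property, .data$range)
  class_iris <- sort(unique(c(
    types$class_iri, edges$domain, edges$range[edges$range_kind == "class"]
  )))
  labels <- graph |>
    dplyr::filter(
      .data$predicate == RDFS_LABEL, .data$object_kind == "literal",
      .data$subject %in% class_iris
    ) |>
    dplyr::distinct(.data$subject, .keep_all = TRUE)
  nodes <- tibble::tibble(
    class_iri = class_iris,
    label = labels$object[match(class_iris, labels$subject)]
  )
  new_schema(nodes, edges)
}

new_schema <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "kg_schema")
}

#' @export
print.kg_schema <- function(x, ...) {
  cat(
    "# Schema graph: ", nrow(x$nodes), " classes, ", nrow(x$edges),
    " property edges (", sum(x$edges$range_kind == "class"),
    " object, ", sum(x$edges$range_kind == "datatype"), " datatype)\n",
    sep = ""
  )
  invisible(x)
}

# Relation edges only (class-to-class), used for query-graph search.
schema_relations <- function(schema) {
  schema$edges[schema$edges$range_kind == "class", , drop = FALSE]
}

#' Attach candidate matches to the schema graph
#'
#' Builds the augmented search graph of the query-graph constructor: one
#' auxiliary leaf node per candidate match, joined to the match's class node
#' by a zero-cost edge, while schema edges cost one hop. Metadata matches
#' (class or property index entries) mark schema nodes/edges directly rather
#' than adding leaves. Matches whose class is absent from the schema are
#' dropped with a diagnostic, mirroring the situation where untyped resources
#' cannot be attached anywhere.
#'
#' @param schema A `kg_schema`.
#' @param matches Tibble of candidate matches (see [group_candidates()]).
#' @return An igraph with vertex attribute `kind` (`"class"`/`"match"`) and
#'   edge weights 0/1; attribute `dropped` lists unattachable matches.
#' @export
attach_candidates <- function(schema, matches) {
  rel <- schema_relations(schema)
  pair <- dplyr::distinct(tibble::tibble(
    from = pmin(rel$domain, rel$range),
    to = pmax(rel$domain, rel$range)
  ))
  pair <- pair[pair$from != pair$to, , drop = FALSE] # self-loops don't aid connectivity
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(schema$nodes),
    name = schema$nodes$class_iri, kind = "class"
  )
  if (nrow(pair) > 0) {
    g <- igraph::add_edges(g, rbind(pair$from, pair$to), weight = 1)
  }
  dropped <- character(0)
  if (!is.null(matches) && nrow(matches) > 0) {
    for (i in seq_len(nrow(matches))) {
      m <- matches[i, ]
      if (m$kind == "property") next # marks edges, not nodes
      if (!m$node_iri %in% schema$nodes$class_iri) {
        dropped <- c(dropped, m$node_iri)
        message(
          "attach_candidates(): match class not in schema, dropped: ",
          m$node_iri
        )
        next
      }
      if (m$kind == "class") next # marks its own schema node
      leaf <- paste0("match:", i)
      g <- igraph::add_vertices(g, 1, name = leaf, kind = "match")
      g <- igraph::add_edges(g, c(leaf, m$node_iri), weight = 0)
    }
  }
  attr(g, "dropped") <- dropped
  g
}

#' Export a schema graph as reified N-Triples
#'
#' Each edge becomes a record node with `rdfs:domain`, `rdfs:range` and a
#' property pointer, so the schema can round-trip through plain RDF tooling.
#'
#' @param schema A `kg_schema`.
#' @param path Output file; omit to get the lines back.
#' @return Lines, invisibly.
#' @export
write_schema_ntriples <- function(schema, path = NULL) {
  e <- schema$edges
  lines <- character(0)
  if (nrow(e) > 0) {
    node <- sprintf("urn:x-schema:edge:%03d", seq_len(nrow(e)))
    lines <- c(
      paste0("<", node, "> <", RDFS_DOMAIN, "> <", e$domain, "> ."),
      paste0("<", node, "> <urn:x-schema:property> <", e$property, "> ."),
      ifelse(
        e$range_kind == "class",
        paste0("<", node, "> <", RDFS_RANGE, "> <", e$range, "> ."),
        paste0("<", node, "> <", RDFS_RANGE, "> <", e$range, "> .")
      )
    )
    lines <- sort(lines)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a schema graph back from its reified N-Triples export
#'
#' @param path File written by [write_schema_ntriples()].
#' @return A `kg_schema` (witness counts are not preserved).
#' @export
read_schema_ntriples <- function(path) {
  g <- read_kg(path, format = "ntriples")
  recs <- tidyr::pivot_wider(
    g[, c("subject", "predicate", "object")],
    names_from = "predicate", values_from = "object"
  )
  edges <- tibble::tibble(
    domain = recs[[RDFS_DOMAIN]],
    property = recs[["urn:x-schema:property"]],
    range = recs[[RDFS_RANGE]],
    range_kind = ifelse(startsWith(recs[[RDFS_RANGE]], XSD), "datatype", "class"),
    n_instances = NA_integer_
  ) |> dplyr::arrange(.data$domain, .data$property, .data$range)
  class_iris <- sort(unique(c(edges$domain, edges$range[edges$range_kind == "class"])))
  new_schema(
    tibble::tibble(class_iri = class_iris, label = NA_character_),
    edges
  )
}

#' Render a schema graph in DOT format
#'
#' @param schema A `kg_schema`.
#' @return A single DOT string (directed graph, one edge per property).
#' @export
schema_to_dot <- function(schema) {
  rel <- schema_relations(schema)
  nodes <- paste0(
    "  \"", iri_local_name(schema$nodes$class_iri), "\";"
  )
  edges <- paste0(
    "  \"", iri_local_name(rel$domain), "\" -> \"", iri_local_name(rel$range),
    "\" [label=\"", iri_local_name(rel$property), "\"];"
  )
  paste(c("digraph schema {", nodes, edges, "}"), collapse = "\n")
}
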