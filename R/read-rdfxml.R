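# RDF/XML reader on top of xml2. Supports the common abbreviated syntax:
# rdf:Description and typed node elements, rdf:about / rdf:ID, property
# elements holding literals (with xml:lang / rdf:datatype), rdf:resource
# references, nested node elements, and rdf:nodeID blank nodes (skolemized).
# rdf:parseType and containers are not supported.

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

parse_rdfxml_file <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop("RDF/XML parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  root <- xml2::xml_root(doc)
  st <- new.env(parent = emptyenv())
  st$rows <- list()
  st$bnode_counter <- 0L
  st$file_tag <- gsub("[^A-Za-z0-9]", "-", basename(path))
  st$base <- xml2::xml_attr(root, "base", default = "")
  for (node in xml2::xml_children(root)) {
    rdfxml_node(st, node)
  }
  rows <- st$rows
  triples <- if (length(rows) == 0) {
    NULL
  } else {
    tibble::tibble(
      subject = vapply(rows, `[[`, "", 1L),
      predicate = vapply(rows, `[[`, "", 2L),
      object = vapply(rows, `[[`, "", 3L),
      object_kind = vapply(rows, `[[`, "", 4L),
      datatype = vapply(rows, `[[`, NA_character_, 5L),
      lang = vapply(rows, `[[`, NA_character_, 6L)
    )
  }
  ns <- xml2::xml_ns(doc)
  prefixes <- stats::setNames(as.character(ns), names(ns))
  prefixes <- prefixes[!grepl("^d[0-9]+$", names(prefixes))]
  list(triples = triples, prefixes = prefixes)
}

rdfxml_qname_iri <- function(node) {
  # Resolve the element's namespace URI + local name into a full IRI.
  url <- xml2::xml_ns(xml2::xml_root(node))
  name <- xml2::xml_name(node, ns = url) # "prefix:local" or "local"
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    paste0(url[[parts[1]]], parts[2])
  } else {
    name
  }
}

rdfxml_attr <- function(node, local) {
  xml2::xml_attr(node, local, default = NA_character_)
}

# Returns the subject IRI of a node element and emits its triples.
rdfxml_node <- function(st, node) {
  about <- rdfxml_attr(node, "about")
  id <- rdfxml_attr(node, "ID")
  node_id <- rdfxml_attr(node, "nodeID")
  subject <- if (!is.na(about)) {
    paste0(st$base, about)
  } else if (!is.na(id)) {
    paste0(st$base, "#", id)
  } else if (!is.na(node_id)) {
    paste0("urn:skolem:", st$file_tag, ":", node_id)
  } else {
    st$bnode_counter <- st$bnode_counter + 1L
    paste0("urn:skolem:", st$file_tag, ":anon", st$bnode_counter)
  }
  type_iri <- rdfxml_qname_iri(node)
  if (type_iri != paste0(RDF_NS, "Description")) {
    st$rows[[length(st$rows) + 1L]] <-
      list(subject, RDF_TYPE, type_iri, "iri", NA_character_, NA_character_)
  }
  for (prop in xml2::xml_children(node)) {
    pred <- rdfxml_qname_iri(prop)
    resource <- rdfxml_attr(prop, "resource")
    if (!is.na(resource)) {
      st$rows[[length(st$rows) + 1L]] <-
        list(subject, pred, paste0(st$base, resource), "iri", NA_character_, NA_character_)
      next
    }
    kids <- xml2::xml_children(prop)
    if (length(kids) > 0) {
      obj <- rdfxml_node(st, kids[[1]])
      st$rows[[length(st$rows) + 1L]] <-
        list(subject, pred, obj, "iri", NA_character_, NA_character_)
      next
    }
    lang <- xml2::xml_attr(prop, "lang", default = NA_character_)
    datatype <- rdfxml_attr(prop, "datatype")
    st$rows[[length(st$rows) + 1L]] <-
      list(subject, pred, xml2::xml_text(prop), "literal", datatype, lang)
  }
  subject
}
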