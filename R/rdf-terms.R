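# Well-known vocabulary IRIs used across the package.
RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
RDFS_DOMAIN <- "http://www.w3.org/2000/01/rdf-schema#domain"
RDFS_RANGE <- "http://www.w3.org/2000/01/rdf-schema#range"
OWL_CLASS <- "http://www.w3.org/2002/07/owl#Class"
OWL_SAMEAS <- "http://www.w3.org/2002/07/owl#sameAs"
RDF_PROPERTY <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#Property"
DCT_DESCRIPTION <- "http://purl.org/dc/terms/description"
XSD <- "http://www.w3.org/2001/XMLSchema#"
XSD_STRING <- paste0(XSD, "string")
XSD_INTEGER <- paste0(XSD, "integer")
XSD_DECIMAL <- paste0(XSD, "decimal")
XSD_DOUBLE <- paste0(XSD, "double")
XSD_BOOLEAN <- paste0(XSD, "boolean")

# Sentinel property for index entries derived from a URI fragment rather than
# a literal property value.
URI_MATCH <- "uri_match"

#' Local name of an IRI
#'
#' The fragment after the last `#` or `/`, used for keyword extraction and
#' SPARQL variable naming.
#'
#' @param iri Character vector of absolute IRIs.
#' @return Character vector of local names.
#' @export
iri_local_name <- function(iri) {
  sub(".*[#/]", "", iri)
}

# Namespace part of an IRI (up to and including the last # or /).
iri_namespace <- function(iri) {
  sub("(.*[#/]).*", "\\1", iri)
}

escape_nt_string <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  x <- gsub("\n", "\\\\n", x)
  x <- gsub("\r", "\\\\r", x)
  x <- gsub("\t", "\\\\t", x)
  x
}

unescape_nt_string <- function(x) {
  vapply(x, function(s) {
    out <- character(0)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      ch <- chars[i]
      if (ch == "\\" && i < n) {
        nxt <- chars[i + 1L]
        rep <- switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t",
          "\"" = "\"", "\\" = "\\",
          "u" = NA_character_, "U" = NA_character_,
          nxt
        )
        if (is.na(rep)) {
          width <- if (nxt == "u") 4L else 8L
          code <- paste(chars[(i + 2L):(i + 1L + width)], collapse = "")
          out <- c(out, intToUtf8(strtoi(code, 16L)))
          i <- i + 2L + width
          next
        }
        out <- c(out, rep)
        i <- i + 2L
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Canonical N-Triples rendering of an object term; doubles as the join key in
# the pattern evaluator (IRIs and literals can never collide).
object_term <- function(object, object_kind, datatype, lang) {
  as.character(ifelse(
    object_kind == "iri",
    paste0("<", object, ">"),
    paste0(
      "\"", escape_nt_string(object), "\"",
      ifelse(!is.na(lang), paste0("@", lang),
        ifelse(!is.na(datatype) & datatype != XSD_STRING,
          paste0("^^<", datatype, ">"), ""
        )
      )
    )
  ))
}
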