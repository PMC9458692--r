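# SPARQL SELECT generation from query graphs, and a strict evaluator for the
# emitted subset (basic graph patterns, OPTIONAL label blocks, FILTER on
# string equality/regex, DISTINCT, LIMIT) so queries run against the local
# triple store through the same nested-loop join oracle the tests use.

#' Serialize a query graph to a SPARQL SELECT query
#'
#' One triple pattern per schema edge, an `rdf:type` pattern per class node,
#' a value pattern plus case-insensitive word-anchored regex FILTER per
#' instance match (so a "brca" match retrieves "BRCA1" and "BRCA2"), OPTIONAL
#' `rdfs:label` patterns for human-readable columns, and any triggered rule
#' bodies as subquery blocks. Variable names derive from class local names
#' (`?drug`, `?disease`), suffixed with a namespace tag on collision
#' (`?drugs_drugbank`, `?drugs_sider`). Output text is deterministic for a
#' fixed graph.
#'
#' @param qg A `kg_query_graph`.
#' @param rules Triggered rules (from [triggered_rules()]) appended as
#'   subquery blocks.
#' @param limit Result limit.
#' @return A single SPARQL string.
#' @export
graph_to_sparql <- function(qg, rules = list(), limit = 1000L) {
  nodes <- query_graph_nodes(qg)
  if (length(nodes) == 0) stop("graph_to_sparql(): empty query graph", call. = FALSE)
  vars <- node_variables(nodes)
  patterns <- character(0)
  value_vars <- character(0)
  required_label_nodes <- character(0)

  for (n in nodes) {
    patterns <- c(patterns, sprintf("  %s <%s> <%s> .", vars[[n]], RDF_TYPE, n))
  }
  e <- qg$edges
  for (i in seq_len(nrow(e))) {
    patterns <- c(patterns, sprintf(
      "  %s <%s> %s .", vars[[e$domain[i]]], e$property[i], vars[[e$range[i]]]
    ))
  }
  m <- qg$matches
  if (!"attr_property" %in% names(m)) m$attr_property <- NA_character_
  for (i in seq_len(nrow(m))) {
    if (m$kind[i] == "attribute") {
      # literal property requested by name: project its value, no filter
      cls_var <- vars[[m$node_iri[i]]]
      val_var <- paste0(
        cls_var, "_",
        gsub(" ", "_", split_fragment(iri_local_name(m$attr_property[i])))
      )
      patterns <- c(patterns, sprintf(
        "  %s <%s> %s .", cls_var, m$attr_property[i], val_var
      ))
      value_vars <- c(value_vars, val_var)
      next
    }
    if (m$kind[i] != "instance") next
    cls_var <- vars[[m$node_iri[i]]]
    rx <- token_regex(m$token[i])
    if (m$property_iri[i] == URI_MATCH) {
      patterns <- c(patterns, sprintf(
        "  FILTER(REGEX(STR(%s), \"%s\", \"i\"))", cls_var, rx
      ))
      next
    }
    val_var <- paste0(
      cls_var, "_",
      gsub(" ", "_", split_fragment(iri_local_name(m$property_iri[i])))
    )
    patterns <- c(patterns, sprintf(
      "  %s <%s> %s .", cls_var, m$property_iri[i], val_var
    ))
    patterns <- c(patterns, sprintf(
      "  FILTER(REGEX(STR(%s), \"%s\", \"i\"))", val_var, rx
    ))
    value_vars <- c(value_vars, val_var)
    if (m$property_iri[i] == RDFS_LABEL) {
      required_label_nodes <- c(required_label_nodes, m$node_iri[i])
    }
  }
  label_vars <- character(0)
  for (n in setdiff(nodes, required_label_nodes)) {
    lv <- paste0(vars[[n]], "_label")
    patterns <- c(patterns, sprintf(
      "  OPTIONAL { %s <%s> %s . }", vars[[n]], RDFS_LABEL, lv
    ))
    label_vars <- c(label_vars, lv)
  }
  for (r in rules) {
    patterns <- c(patterns, paste0("  { ", r$body, " }"))
  }
  projection <- unique(c(unlist(vars[nodes]), value_vars, label_vars))
  paste0(
    "SELECT DISTINCT ", paste(projection, collapse = " "), "\nWHERE {\n",
    paste(patterns, collapse = "\n"),
    "\n}\nLIMIT ", as.integer(limit), "\n"
  )
}

query_graph_nodes <- function(qg) {
  m <- qg$matches
  sort(unique(c(
    qg$edges$domain, qg$edges$range,
    m$node_iri[m$kind != "property"]
  )))
}

# ?variable per class node; collisions disambiguated by a namespace tag.
node_variables <- function(nodes) {
  base <- gsub(" ", "_", split_fragment(iri_local_name(nodes)))
  base[!nzchar(base)] <- "x"
  dup <- base %in% base[duplicated(base)]
  ns_tag <- vapply(nodes, function(n) {
    parts <- strsplit(sub("[#/]+$", "", iri_namespace(n)), "[/#]")[[1]]
    tag <- parts[length(parts)]
    gsub("[^a-z0-9]", "", tolower(tag))
  }, "", USE.NAMES = FALSE)
  base[dup] <- paste0(base[dup], "_", ns_tag[dup])
  stats::setNames(as.list(paste0("?", base)), nodes)
}

# word-start-anchored regex for a (possibly multi-word) normalized token
token_regex <- function(token) {
  words <- strsplit(token, " ", fixed = TRUE)[[1]]
  words <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", words)
  paste0("\\\\b", paste(words, collapse = "[^a-z0-9]+"))
}

#' Parse a SPARQL SELECT query of the emitted subset
#'
#' Strict recursive parse of `SELECT DISTINCT ... WHERE { ... } LIMIT n`
#' with triple patterns, `OPTIONAL { ... }` blocks, plain `{ ... }` subquery
#' blocks and `FILTER(REGEX(STR(?v), "re", "i"))` /
#' `FILTER(STR(?v) = "x")` constraints. Anything else is a parse error, which
#' doubles as the grammar check on generated queries.
#'
#' @param text SPARQL string.
#' @return List with `select`, `distinct`, `patterns` (pattern tibble),
#'   `optionals` (list of pattern tibbles), `filters`, `limit`.
#' @export
parse_sparql <- function(text) {
  src <- gsub("[\n\t]", " ", text)
  m <- regmatches(src, regexec(
    "^\\s*SELECT\\s+(DISTINCT\\s+)?((?:\\?[A-Za-z0-9_]+\\s*)+)\\s*WHERE\\s*\\{(.*)\\}\\s*(LIMIT\\s+([0-9]+))?\\s*$",
    src,
    perl = TRUE
  ))[[1]]
  if (length(m) == 0) stop("parse_sparql(): not a SELECT query of the supported form", call. = FALSE)
  select <- strsplit(trimws(m[3]), "\\s+")[[1]]
  distinct <- nzchar(m[2])
  limit <- if (nzchar(m[6])) as.integer(m[6]) else NA_integer_
  body <- m[4]
  parsed <- parse_group(body)
  list(
    select = select, distinct = distinct, patterns = parsed$patterns,
    optionals = parsed$optionals, filters = parsed$filters, limit = limit
  )
}

parse_group <- function(body) {
  patterns <- list()
  optionals <- list()
  filters <- list()
  pos <- 1L
  n <- nchar(body)
  skip_ws <- function() {
    while (pos <= n && grepl("^\\s$", substr(body, pos, pos))) pos <<- pos + 1L
  }
  take_balanced_braces <- function() {
    stopifnot(substr(body, pos, pos) == "{")
    depth <- 0L
    start <- pos
    in_str <- FALSE
    while (pos <= n) {
      ch <- substr(body, pos, pos)
      if (ch == "\"" && substr(body, pos - 1L, pos - 1L) != "\\") in_str <- !in_str
      if (!in_str) {
        if (ch == "{") depth <- depth + 1L
        if (ch == "}") {
          depth <- depth - 1L
          if (depth == 0L) {
            pos <<- pos + 1L
            return(substr(body, start + 1L, pos - 2L))
          }
        }
      }
      pos <- pos + 1L
    }
    stop("parse_sparql(): unbalanced braces", call. = FALSE)
  }
  repeat {
    skip_ws()
    if (pos > n) break
    rest <- substr(body, pos, n)
    if (grepl("^OPTIONAL\\s*\\{", rest)) {
      pos <- pos + nchar(regmatches(rest, regexpr("^OPTIONAL\\s*", rest)))
      inner <- take_balanced_braces()
      sub <- parse_group(inner)
      if (length(sub$filters) > 0 || length(sub$optionals) > 0) {
        stop("parse_sparql(): nested constructs inside OPTIONAL are not supported", call. = FALSE)
      }
      optionals[[length(optionals) + 1L]] <- sub$patterns
      next
    }
    if (grepl("^FILTER\\s*\\(", rest)) {
      fm <- regmatches(rest, regexec(
        "^FILTER\\s*\\(\\s*REGEX\\s*\\(\\s*STR\\s*\\(\\s*(\\?[A-Za-z0-9_]+)\\s*\\)\\s*,\\s*\"((?:[^\"\\\\]|\\\\.)*)\"\\s*(?:,\\s*\"([a-z]*)\"\\s*)?\\)\\s*\\)",
        rest,
        perl = TRUE
      ))[[1]]
      if (length(fm) > 0) {
        filters[[length(filters) + 1L]] <- list(
          type = "regex", var = fm[2],
          pattern = gsub("\\\\\\\\", "\\\\", fm[3]),
          ignore_case = grepl("i", fm[4])
        )
        pos <- pos + nchar(fm[1])
        next
      }
      fm <- regmatches(rest, regexec(
        "^FILTER\\s*\\(\\s*STR\\s*\\(\\s*(\\?[A-Za-z0-9_]+)\\s*\\)\\s*=\\s*\"((?:[^\"\\\\]|\\\\.)*)\"\\s*\\)",
        rest,
        perl = TRUE
      ))[[1]]
      if (length(fm) > 0) {
        filters[[length(filters) + 1L]] <- list(
          type = "equals", var = fm[2], value = unescape_nt_string(fm[3])
        )
        pos <- pos + nchar(fm[1])
        next
      }
      stop("parse_sparql(): unsupported FILTER form", call. = FALSE)
    }
    if (substr(body, pos, pos) == "{") {
      inner <- take_balanced_braces()
      sub <- parse_group(inner)
      # subquery blocks (rule bodies) are conjunctive: merge their patterns
      patterns <- c(patterns, list(sub$patterns))
      filters <- c(filters, sub$filters)
      optionals <- c(optionals, sub$optionals)
      next
    }
    # a triple pattern ending in '.'
    pm <- regmatches(rest, regexec(
      "^(\\S+)\\s+(\\S+)\\s+((?:\"(?:[^\"\\\\]|\\\\.)*\"(?:@[A-Za-z-]+|\\^\\^<[^>]+>)?)|\\S+)\\s*\\.",
      rest,
      perl = TRUE
    ))[[1]]
    if (length(pm) == 0) {
      stop(
        "parse_sparql(): cannot parse near: ",
        substr(rest, 1, 40), call. = FALSE
      )
    }
    patterns[[length(patterns) + 1L]] <- tibble::tibble(
      subject = parse_term(pm[2], "subject"),
      predicate = parse_term(pm[3], "predicate"),
      object = parse_term(pm[4], "object")
    )
    pos <- pos + nchar(pm[1])
  }
  list(
    patterns = dplyr::bind_rows(patterns),
    optionals = optionals, filters = filters
  )
}

parse_term <- function(tok, position) {
  if (startsWith(tok, "?")) {
    return(tok)
  }
  if (tok == "a") {
    return(RDF_TYPE)
  }
  if (grepl("^<[^>]+>$", tok)) {
    return(substr(tok, 2, nchar(tok) - 1))
  }
  if (startsWith(tok, "\"")) {
    if (position != "object") stop("parse_sparql(): literal in ", position, " position", call. = FALSE)
    return(tok) # already N-Triples-style, the evaluator's literal form
  }
  stop("parse_sparql(): unsupported term '", tok, "' in ", position, call. = FALSE)
}

#' Execute a SPARQL SELECT query on a local knowledge graph
#'
#' Evaluates the parsed query through [match_pattern()]: base patterns as a
#' nested-loop join, FILTERs on the string form of bindings, OPTIONAL blocks
#' as left joins. Literal bindings are returned as plain lexical forms, IRIs
#' as IRI strings.
#'
#' @param graph A [kg()] object.
#' @param text SPARQL string (emitted subset, see [parse_sparql()]).
#' @return Tibble with one column per projected variable (without `?`),
#'   deterministically ordered.
#' @export
run_sparql <- function(graph, text) {
  q <- parse_sparql(text)
  if (nrow(q$patterns) == 0) stop("run_sparql(): no triple patterns", call. = FALSE)
  bindings <- match_pattern(graph, q$patterns)
  for (f in q$filters) {
    v <- sub("^\\?", "", f$var)
    if (!v %in% names(bindings)) next
    str_val <- term_to_string(bindings[[v]])
    keep <- if (f$type == "regex") {
      grepl(f$pattern, str_val, ignore.case = f$ignore_case, perl = TRUE)
    } else {
      str_val == f$value
    }
    bindings <- bindings[keep, , drop = FALSE]
  }
  for (opt in q$optionals) {
    if (nrow(opt) == 0) next
    extra <- match_pattern(graph, opt)
    shared <- intersect(names(bindings), names(extra))
    bindings <- if (length(shared) > 0) {
      dplyr::left_join(bindings, extra, by = shared, relationship = "many-to-many")
    } else {
      dplyr::cross_join(bindings, extra)
    }
  }
  vars <- sub("^\\?", "", q$select)
  for (v in setdiff(vars, names(bindings))) bindings[[v]] <- NA_character_
  out <- bindings[, vars, drop = FALSE]
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), term_to_string))
  if (q$distinct) out <- dplyr::distinct(out)
  out <- dplyr::arrange(out, dplyr::across(dplyr::everything()))
  if (!is.na(q$limit)) out <- utils::head(out, q$limit)
  out
}

# binding values -> human-readable strings (literal lexical form, IRI as-is)
term_to_string <- function(x) {
  lit <- !is.na(x) & startsWith(x, "\"")
  x[lit] <- unescape_nt_string(sub("^\"((?:[^\"\\\\]|\\\\.)*)\".*$", "\\1", x[lit], perl = TRUE))
  x
}
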