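# Independent oracle implementations used to cross-check the package:
# deliberately coded from scratch (plain loops, or an unrelated library)
# rather than reusing package internals.

# exhaustive backtracking evaluator for basic graph patterns
oracle_match <- function(graph, patterns) {
  graph <- as.data.frame(graph)
  patterns <- as.data.frame(patterns)
  term_of <- function(row) {
    if (row$object_kind == "iri") {
      return(row$object)
    }
    suffix <- if (!is.na(row$lang)) {
      paste0("@", row$lang)
    } else if (!is.na(row$datatype) && row$datatype != "http://www.w3.org/2001/XMLSchema#string") {
      paste0("^^<", row$datatype, ">")
    } else {
      ""
    }
    paste0("\"", row$object, "\"", suffix)
  }
  results <- list()
  recurse <- function(i, env) {
    if (i > nrow(patterns)) {
      results[[length(results) + 1L]] <<- env
      return(invisible())
    }
    pat <- patterns[i, ]
    for (t in seq_len(nrow(graph))) {
      row <- graph[t, ]
      env2 <- env
      ok <- TRUE
      for (spec in list(
        c(pat$subject, row$subject),
        c(pat$predicate, row$predicate),
        c(pat$object, term_of(row))
      )) {
        want <- spec[1]
        have <- spec[2]
        if (startsWith(want, "?")) {
          v <- substring(want, 2)
          if (!is.null(env2[[v]]) && env2[[v]] != have) {
            ok <- FALSE
            break
          }
          env2[[v]] <- have
        } else if (want != have) {
          ok <- FALSE
          break
        }
      }
      if (ok) recurse(i + 1L, env2)
    }
  }
  recurse(1L, list())
  vars <- unique(unlist(patterns))
  vars <- substring(vars[startsWith(vars, "?")], 2)
  if (length(results) == 0) {
    out <- as.data.frame(matrix(character(0), ncol = length(vars)))
    names(out) <- vars
    return(tibble::as_tibble(out))
  }
  out <- do.call(rbind, lapply(results, function(env) {
    as.data.frame(env[vars], col.names = vars, stringsAsFactors = FALSE)
  }))
  out <- dplyr::distinct(tibble::as_tibble(out))
  dplyr::arrange(out, dplyr::across(dplyr::everything()))
}

# PageRank oracle via igraph (PRPACK), on the same resource graph definition
oracle_pagerank <- function(graph, damping = 0.85) {
  edges <- graph[graph$object_kind == "iri", c("subject", "object")]
  nodes <- sort(unique(c(graph$subject, edges$object)))
  ig <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  pr <- igraph::page_rank(ig, damping = damping)$vector
  tibble::tibble(uri = names(pr), pagerank = as.numeric(pr)) |>
    dplyr::arrange(uri)
}

# brute-force schema extraction: scan every triple against every type pair
oracle_schema_edges <- function(graph) {
  g <- as.data.frame(graph)
  types <- g[g$predicate == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type" &
    g$object_kind == "iri", c("subject", "object")]
  rows <- list()
  body <- g[g$predicate != "http://www.w3.org/1999/02/22-rdf-syntax-ns#type", ]
  for (i in seq_len(nrow(body))) {
    tr <- body[i, ]
    ts <- types$object[types$subject == tr$subject]
    for (dcls in ts) {
      if (tr$object_kind == "iri") {
        for (rcls in types$object[types$subject == tr$object]) {
          rows[[length(rows) + 1L]] <- c(dcls, tr$predicate, rcls, "class")
        }
      } else {
        dt <- if (is.na(tr$datatype)) "http://www.w3.org/2001/XMLSchema#string" else tr$datatype
        rows[[length(rows) + 1L]] <- c(dcls, tr$predicate, dt, "datatype")
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      domain = character(0), property = character(0),
      range = character(0), range_kind = character(0)
    ))
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(
    domain = m[, 1], property = m[, 2], range = m[, 3], range_kind = m[, 4]
  )
  dplyr::arrange(dplyr::distinct(out), domain, property, range)
}

# exhaustive Steiner optimum on small unit-weight graphs: smallest connected
# vertex superset of the terminals, cost = |S| - 1
oracle_steiner_cost <- function(g, terminals) {
  vs <- igraph::V(g)$name
  others <- setdiff(vs, terminals)
  best <- Inf
  for (k in 0:length(others)) {
    for (extra in combn_list(others, k)) {
      s <- c(terminals, extra)
      sub <- igraph::induced_subgraph(g, s)
      if (igraph::is_connected(sub)) best <- min(best, length(s) - 1)
    }
    if (is.finite(best)) break # supersets can only cost more in vertices
  }
  best
}

combn_list <- function(x, k) {
  if (k == 0) {
    return(list(character(0)))
  }
  if (length(x) < k) {
    return(list())
  }
  apply(utils::combn(x, k), 2, identity, simplify = FALSE)
}

# random connected unit-weight igraph for Steiner checks
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    ig <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(ig)) break
  }
  igraph::V(ig)$name <- paste0("n", seq_len(n))
  igraph::E(ig)$weight <- 1
  ig
}

random_tree_graph <- function(n, seed) {
  set.seed(seed)
  parents <- vapply(2:n, function(i) sample(seq_len(i - 1), 1), 0L)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(parents, 2:n))
  igraph::V(ig)$name <- paste0("n", seq_len(n))
  igraph::E(ig)$weight <- 1
  ig
}

# tiny Turtle fixture text used across parser tests
fig_ttl_text <- function() {
  paste(
    "@prefix ds: <http://example.org/diseasome/> .",
    "@prefix db: <http://example.org/drugbank/> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "ds:migraine a ds:diseases ;",
    "  rdfs:label \"migraine\" ;",
    "  ds:possibleDrug db:DB01050 .",
    "db:DB01050 a db:drugs ;",
    "  rdfs:label \"Ibuprofen\"@en ;",
    "  db:weight 206.29 .",
    sep = "\n"
  )
}

write_temp_ttl <- function(text, ext = ".ttl") {
  path <- tempfile(fileext = ext)
  writeLines(text, path)
  path
}
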