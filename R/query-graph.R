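# Query graph construction: for each combination of one candidate per token,
# connect the candidates' classes through a minimal subgraph of the schema
# (approximate Steiner tree), enumerate the property variants of each tree
# edge, and score each resulting graph by the sum of its covered candidates'
# scores.

#' Approximate Steiner tree on a weighted undirected graph
#'
#' Classical 2-approximation: shortest-path metric closure over the
#' terminals, minimum spanning tree of the closure, expansion back to graph
#' edges, pruning of non-terminal leaves.
#'
#' @param g Undirected igraph with a `weight` edge attribute.
#' @param terminals Vertex names to connect.
#' @return `NULL` when the terminals are not connected, otherwise a list
#'   with `nodes`, `edges` (two-column matrix of vertex names) and `cost`.
#' @export
steiner_tree <- function(g, terminals) {
  terminals <- unique(terminals)
  stopifnot(all(terminals %in% igraph::V(g)$name))
  if (length(terminals) == 1) {
    return(list(nodes = terminals, edges = matrix(character(0), ncol = 2), cost = 0))
  }
  d <- igraph::distances(g, v = terminals, to = terminals)
  if (any(is.infinite(d))) {
    return(NULL)
  }
  closure <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(closure, weights = igraph::E(closure)$weight)
  edge_set <- character(0)
  ends <- igraph::as_edgelist(mst)
  for (i in seq_len(nrow(ends))) {
    sp <- igraph::shortest_paths(g,
      from = ends[i, 1], to = ends[i, 2],
      weights = igraph::E(g)$weight, output = "epath"
    )
    edge_set <- union(edge_set, igraph::as_ids(sp$epath[[1]]))
  }
  sub <- igraph::subgraph_from_edges(g, igraph::E(g)[igraph::as_ids(igraph::E(g)) %in% edge_set],
    delete.vertices = TRUE
  )
  # prune non-terminal leaves until fixpoint
  repeat {
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg <= 1 & !names(deg) %in% terminals]
    if (length(drop) == 0) break
    sub <- igraph::delete_vertices(sub, drop)
  }
  list(
    nodes = igraph::V(sub)$name,
    edges = igraph::as_edgelist(sub),
    cost = sum(igraph::E(sub)$weight %||% rep(1, igraph::ecount(sub)))
  )
}

# Collapsed class graph: one undirected unit-weight edge per class pair
# connected by at least one property.
collapsed_class_graph <- function(schema) {
  rel <- schema_relations(schema)
  pair <- dplyr::distinct(tibble::tibble(
    from = pmin(rel$domain, rel$range), to = pmax(rel$domain, rel$range)
  ))
  pair <- pair[pair$from != pair$to, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nrow(schema$nodes), name = schema$nodes$class_iri)
  if (nrow(pair) > 0) g <- igraph::add_edges(g, rbind(pair$from, pair$to), weight = 1)
  g
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Build candidate query graphs for ranked matches
#'
#' For each combination of one candidate match per token (visited best-first
#' by candidate score sum, capped at `max_combinations`): attach the matches
#' to the schema, find the minimal connecting subgraph over the matched
#' classes, and emit one query graph per property variant when classes are
#' connected by several properties (all variants matter: equal-length
#' subgraphs can have opposite meanings). Property matches force their edge
#' into the graph. Combinations whose classes are not connected in the
#' schema are skipped with a diagnostic.
#'
#' @param schema A `kg_schema`.
#' @param candidates List of per-token candidate tibbles (each from
#'   [score_candidates()]); tokens with no surviving candidate are
#'   unconstrained and ignored.
#' @param max_combinations Combination cap (the worst case is
#'   `top_n ^ n_tokens`).
#' @param variant_cap Property-variant cap per combination.
#' @return List of `kg_query_graph` objects (deduplicated), with attributes
#'   `n_combinations` (enumerated) and `n_skipped`.
#' @export
build_query_graphs <- function(schema, candidates, max_combinations = 64L,
                               variant_cap = 16L) {
  candidates <- candidates[vapply(candidates, nrow, 0L) > 0]
  if (length(candidates) == 0) {
    out <- list()
    attr(out, "n_combinations") <- 0L
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  g <- collapsed_class_graph(schema)
  rel <- schema_relations(schema)
  dt <- schema$edges[schema$edges$range_kind == "datatype", , drop = FALSE]
  known <- igraph::V(g)$name

  grid <- expand.grid(lapply(candidates, function(m) seq_len(nrow(m))))
  score_mat <- matrix(0, nrow(grid), length(candidates))
  for (j in seq_along(candidates)) {
    score_mat[, j] <- candidates[[j]]$score[grid[[j]]]
  }
  score_sum <- rowSums(score_mat)
  ord <- order(-score_sum, do.call(paste, grid))
  grid <- grid[utils::head(ord, max_combinations), , drop = FALSE]

  graphs <- list()
  seen <- character(0)
  n_skipped <- 0L
  for (r in seq_len(nrow(grid))) {
    combo <- dplyr::bind_rows(lapply(
      seq_along(candidates),
      function(j) candidates[[j]][grid[r, j], , drop = FALSE]
    ))
    built <- build_one_combination(combo, g, rel, dt, known, variant_cap)
    if (is.null(built)) {
      n_skipped <- n_skipped + 1L
      next
    }
    for (qg in built) {
      if (qg$canonical %in% seen) next
      seen <- c(seen, qg$canonical)
      graphs[[length(graphs) + 1L]] <- qg
    }
  }
  attr(graphs, "n_combinations") <- nrow(grid)
  attr(graphs, "n_skipped") <- n_skipped
  graphs
}

build_one_combination <- function(combo, g, rel, dt, known, variant_cap) {
  terminals <- character(0)
  forced <- rel[0, , drop = FALSE]
  if (!"attr_property" %in% names(combo)) combo$attr_property <- NA_character_
  other_anchors <- combo$node_iri[combo$kind != "property"]
  for (i in seq_len(nrow(combo))) {
    m <- combo[i, ]
    if (m$kind == "property") {
      hits <- rel[rel$property == m$node_iri & rel$domain != rel$range, , drop = FALSE]
      if (nrow(hits) == 0) {
        # literal-valued property (e.g. a description attribute): anchor the
        # match to the property's domain class, preferring one the other
        # tokens already touch
        doms <- sort(unique(dt$domain[dt$property == m$node_iri]))
        if (length(doms) == 0) {
          message("build_query_graphs(): property match has no schema edge: ", m$node_iri)
          return(NULL)
        }
        dom <- if (any(doms %in% other_anchors)) doms[doms %in% other_anchors][1] else doms[1]
        combo$kind[i] <- "attribute"
        combo$attr_property[i] <- m$node_iri
        combo$node_iri[i] <- dom
        terminals <- c(terminals, dom)
        next
      }
      hits <- hits[1, , drop = FALSE] # deterministic: first (sorted) class pair
      forced <- dplyr::bind_rows(forced, hits)
      terminals <- c(terminals, hits$domain, hits$range)
    } else {
      if (!m$node_iri %in% known) {
        message("build_query_graphs(): match class not in schema, skipped: ", m$node_iri)
        return(NULL)
      }
      terminals <- c(terminals, m$node_iri)
    }
  }
  terminals <- unique(terminals)
  tree <- steiner_tree(g, terminals)
  if (is.null(tree)) {
    message(
      "build_query_graphs(): no connected subgraph covers {",
      paste(iri_local_name(terminals), collapse = ", "), "}"
    )
    return(NULL)
  }
  pairs <- if (nrow(tree$edges) > 0) {
    tibble::tibble(a = tree$edges[, 1], b = tree$edges[, 2])
  } else {
    tibble::tibble(a = character(0), b = character(0))
  }
  # force property-match edges into the slot set
  for (i in seq_len(nrow(forced))) {
    k <- pair_key(forced$domain[i], forced$range[i])
    if (!k %in% pair_key(pairs$a, pairs$b)) {
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(a = forced$domain[i], b = forced$range[i]))
    }
  }
  # options per slot: all directed schema edges between the two classes,
  # restricted to the forced property where one applies
  slot_options <- lapply(seq_len(nrow(pairs)), function(i) {
    k <- pair_key(pairs$a[i], pairs$b[i])
    opts <- rel[pair_key(rel$domain, rel$range) == k, , drop = FALSE]
    fk <- forced[pair_key(forced$domain, forced$range) == k, , drop = FALSE]
    if (nrow(fk) > 0) opts <- opts[opts$property %in% fk$property, , drop = FALSE]
    dplyr::arrange(opts, .data$domain, .data$property, .data$range)
  })
  if (any(vapply(slot_options, nrow, 0L) == 0)) {
    return(NULL)
  }
  if (length(slot_options) == 0) { # all matches on one class: zero-hop graph
    return(list(new_query_graph(rel[0, c("domain", "property", "range")], combo)))
  }
  idx <- expand.grid(lapply(slot_options, function(o) seq_len(nrow(o))))
  idx <- utils::head(idx[do.call(order, idx), , drop = FALSE], variant_cap)
  lapply(seq_len(nrow(idx)), function(v) {
    edges <- dplyr::bind_rows(lapply(
      seq_along(slot_options),
      function(s) slot_options[[s]][idx[v, s], c("domain", "property", "range")]
    ))
    new_query_graph(edges, combo)
  })
}

new_query_graph <- function(edges, matches) {
  edges <- dplyr::arrange(edges, .data$domain, .data$property, .data$range)
  if (!"attr_property" %in% names(matches)) matches$attr_property <- NA_character_
  attr_hops <- sum(matches$kind %in% c("instance", "attribute"))
  canonical <- paste(
    c(
      paste(edges$domain, edges$property, edges$range, sep = "|"),
      sort(paste(matches$kind, matches$node_iri, matches$property_iri,
        matches$matched_key, matches$attr_property,
        sep = "|"
      ))
    ),
    collapse = ";"
  )
  structure(
    list(
      edges = edges,
      matches = matches,
      schema_hops = nrow(edges),
      attr_hops = attr_hops,
      hop_count = nrow(edges) + attr_hops,
      score = sum(matches$score),
      canonical = canonical
    ),
    class = "kg_query_graph"
  )
}

#' @export
print.kg_query_graph <- function(x, ...) {
  cat("# Query graph: ", x$hop_count, " hops (", x$schema_hops,
    " schema + ", x$attr_hops, " attribute), score ", round(x$score, 3), "\n",
    sep = ""
  )
  if (nrow(x$edges) > 0) {
    cat(paste0(
      "  ", iri_local_name(x$edges$domain), " --", iri_local_name(x$edges$property),
      "--> ", iri_local_name(x$edges$range)
    ), sep = "\n")
  }
  cat(paste0(
    "  [", x$matches$kind, "] ", x$matches$token, " -> ",
    iri_local_name(x$matches$node_iri)
  ), sep = "\n")
  invisible(x)
}

#' Rank candidate query graphs
#'
#' `score_sum` (the default) orders by descending sum of covered match
#' scores, breaking ties by fewer hops and then by canonical text — the
#' graph that best covers the question wins even when a smaller graph
#' exists. `min_subgraph` is the ablation ordering: smallest subgraph first
#' (schema hops, then total hops), ties by descending string-similarity sum.
#'
#' @param graphs List of `kg_query_graph`s.
#' @param mode `"score_sum"` or `"min_subgraph"`.
#' @return Tibble: `rank`, `score`, `hop_count`, `schema_hops`, `graph`
#'   (list column).
#' @export
rank_query_graphs <- function(graphs, mode = c("score_sum", "min_subgraph")) {
  mode <- match.arg(mode)
  if (length(graphs) == 0) stop("rank_query_graphs(): no query graphs", call. = FALSE)
  tab <- tibble::tibble(
    score = vapply(graphs, `[[`, 0, "score"),
    hop_count = vapply(graphs, `[[`, 0L, "hop_count"),
    schema_hops = vapply(graphs, `[[`, 0L, "schema_hops"),
    sim_sum = vapply(graphs, function(g) sum(g$matches$string_sim), 0),
    canonical = vapply(graphs, `[[`, "", "canonical"),
    graph = graphs
  )
  ord <- if (mode == "score_sum") {
    order(-tab$score, tab$hop_count, tab$canonical)
  } else {
    order(tab$schema_hops, tab$hop_count, -tab$sim_sum, tab$canonical)
  }
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab[, c("rank", "score", "hop_count", "schema_hops", "sim_sum", "canonical", "graph")]
}

#' Find the custom rules triggered by a question
#'
#' A rule fires when all its trigger keywords occur (after normalization)
#' among the question's normalized words; triggered rules contribute their
#' body as a subquery block during SPARQL generation.
#'
#' @param question Question text.
#' @param rules List of rules: each a list with `name`, `trigger_keywords`,
#'   `head` (projection variables) and `body` (WHERE-clause fragment).
#' @param stopwords Stopwords applied during question normalization.
#' @return The triggered subset of `rules` (possibly empty).
#' @export
triggered_rules <- function(question, rules, stopwords = default_stopwords()) {
  if (length(rules) == 0) {
    return(list())
  }
  words <- normalize_words(question, stopwords = stopwords)[[1]]
  Filter(function(rule) {
    keys <- unlist(normalize_words(rule$trigger_keywords))
    length(keys) > 0 && all(keys %in% words)
  }, rules)
}

#' Read a rules file
#'
#' YAML list of `{name, trigger_keywords, head, body}` records.
#'
#' @param path Rules file path.
#' @return List of rules.
#' @export
read_rules <- function(path) {
  rules <- yaml::read_yaml(path)
  for (r in rules) {
    stopifnot(!is.null(r$name), !is.null(r$trigger_keywords), !is.null(r$body))
  }
  rules
}
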