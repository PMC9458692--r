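fig2_sys <- local({
  suppressMessages(qa_system(build_fixture("fig2_biomed")))
})

candidates_for <- function(sys, question, top_n = 3, use_pagerank = TRUE) {
  tokens <- tokenize_question(sys$index, question)
  cands <- lapply(seq_len(nrow(tokens)), function(i) {
    score_candidates(
      group_candidates(tokens$entries[[i]], tokens$token[i]),
      top_n = top_n, use_pagerank = use_pagerank, max_pagerank = sys$max_pagerank
    )
  })
  names(cands) <- tokens$token
  cands
}

test_that("the asthma question yields a 2-hop Drug-Disease query graph", {
  cands <- candidates_for(fig2_sys, "What are the drugs for asthma?")
  graphs <- suppressMessages(build_query_graphs(fig2_sys$schema, cands))
  ranked <- rank_query_graphs(graphs, mode = "score_sum")
  top <- ranked$graph[[1]]
  expect_equal(top$hop_count, 2L)
  expect_equal(top$schema_hops, 1L)
  e <- top$edges
  expect_setequal(
    c(e$domain, e$range),
    c("http://example.org/drugbank/drugs", "http://example.org/diseasome/diseases")
  )
  expect_true(e$property %in% c(
    "http://example.org/diseasome/possibleDiseaseTarget",
    "http://example.org/diseasome/possibleDrug"
  ))
  covered <- top$matches
  expect_true("http://example.org/diseasome/diseases" %in%
    covered$node_iri[covered$kind == "instance"])
})

test_that("tokens landing on one class give a zero-hop single-node graph", {
  cands <- candidates_for(fig2_sys, "show all drugs")
  cands <- lapply(cands, function(m) m[m$kind == "class", , drop = FALSE][1, ])
  graphs <- suppressMessages(build_query_graphs(fig2_sys$schema, cands))
  expect_equal(min(vapply(graphs, `[[`, 0L, "schema_hops")), 0L)
  zero <- graphs[[which.min(vapply(graphs, `[[`, 0L, "schema_hops"))]]
  expect_equal(nrow(zero$edges), 0L)
  expect_equal(zero$hop_count, 0L)
})

test_that("multigraph class pairs enumerate one query graph per property variant", {
  # expression graph: Gene and AnatomicalEntity joined by two disjoint properties
  cands <- list(
    gene = tibble::tibble(
      token = "gene", kind = "class", class_iri = "http://www.w3.org/2002/07/owl#Class",
      property_iri = "uri_match", node_iri = "http://example.org/bgee/Gene",
      members = list("http://example.org/bgee/Gene"), n_members = 1L,
      matched_key = "gene", string_sim = 1, pagerank = 0.1, score = 1.1, rank = 1L
    ),
    lung = tibble::tibble(
      token = "lung", kind = "instance", class_iri = "http://example.org/bgee/AnatomicalEntity",
      property_iri = "http://www.w3.org/2000/01/rdf-schema#label",
      node_iri = "http://example.org/bgee/AnatomicalEntity",
      members = list("http://example.org/bgee/UBERON_0002048"), n_members = 1L,
      matched_key = "lung", string_sim = 1, pagerank = 0.05, score = 1.05, rank = 1L
    )
  )
  graphs <- suppressMessages(build_query_graphs(fig2_sys$schema, cands))
  props <- vapply(graphs, function(g) g$edges$property[1], "")
  expect_setequal(props, c(
    "http://example.org/bgee/isAbsentIn",
    "http://example.org/bgee/isExpressedIn"
  ))
  expect_equal(length(unique(vapply(graphs, `[[`, 0L, "hop_count"))), 1L)
})

test_that("every emitted query graph is connected and covers one match per token", {
  for (q in c(
    "What are the drugs for asthma?",
    "Which genes are expressed in the lung?",
    "side effects of drugs"
  )) {
    cands <- candidates_for(fig2_sys, q)
    graphs <- suppressMessages(build_query_graphs(fig2_sys$schema, cands))
    for (g in graphs) {
      expect_equal(nrow(g$matches), length(cands))
      expect_equal(
        g$hop_count,
        g$schema_hops + sum(g$matches$kind %in% c("instance", "attribute"))
      )
      nodes <- unique(c(g$edges$domain, g$edges$range, g$matches$node_iri[g$matches$kind != "property"]))
      if (nrow(g$edges) > 0) {
        ig <- igraph::graph_from_data_frame(
          g$edges[, c("domain", "range")],
          directed = FALSE, vertices = nodes
        )
        expect_true(igraph::is_connected(ig))
      } else {
        expect_equal(length(nodes), 1L)
      }
    }
    expect_lte(
      attr(graphs, "n_combinations"),
      prod(vapply(cands, function(m) max(1L, nrow(m)), 0L))
    )
  }
})

test_that("steiner trees are optimal on trees and within 2x optimum generally", {
  for (seed in 1:50) {
    g <- random_tree_graph(n = sample(5:8, 1), seed = seed)
    terminals <- sample(igraph::V(g)$name, sample(2:4, 1))
    tree <- steiner_tree(g, terminals)
    expect_equal(tree$cost, oracle_steiner_cost(g, terminals))
  }
  for (seed in 1:50) {
    g <- random_connected_graph(n = sample(5:8, 1), p = 0.45, seed = seed + 1000)
    terminals <- sample(igraph::V(g)$name, sample(2:4, 1))
    tree <- steiner_tree(g, terminals)
    opt <- oracle_steiner_cost(g, terminals)
    expect_gte(tree$cost, opt)
    expect_lte(tree$cost, 2 * opt)
    expect_true(all(terminals %in% tree$nodes))
  }
})

test_that("disconnected combinations are skipped with a diagnostic", {
  schema <- extract_schema(build_fixture("fig2_biomed"))
  cands <- list(
    a = tibble::tibble(
      token = "gene", kind = "class", class_iri = "http://www.w3.org/2002/07/owl#Class",
      property_iri = "uri_match", node_iri = "http://example.org/bgee/Gene",
      members = list("http://example.org/bgee/Gene"), n_members = 1L,
      matched_key = "gene", string_sim = 1, pagerank = 0.1, score = 1, rank = 1L
    ),
    b = tibble::tibble(
      token = "drug", kind = "class", class_iri = "http://www.w3.org/2002/07/owl#Class",
      property_iri = "uri_match", node_iri = "http://example.org/drugbank/drugs",
      members = list("http://example.org/drugbank/drugs"), n_members = 1L,
      matched_key = "drug", string_sim = 1, pagerank = 0.1, score = 1, rank = 1L
    )
  )
  expect_message(
    graphs <- build_query_graphs(schema, cands),
    "no connected subgraph"
  )
  expect_equal(length(graphs), 0L)
  expect_equal(attr(graphs, "n_skipped"), 1L)
})

test_that("ranking modes order by score sum versus minimal subgraph", {
  make_graph <- function(edges, matches) kgask:::new_query_graph(edges, matches)
  match_row <- function(token, kind, score, sim = 1) {
    tibble::tibble(
      token = token, kind = kind, class_iri = "http://example.org/C",
      property_iri = "p", node_iri = "http://example.org/C",
      members = list("m"), n_members = 1L, matched_key = token,
      string_sim = sim, pagerank = 0, score = score
    )
  }
  no_edges <- tibble::tibble(
    domain = character(0), property = character(0), range = character(0)
  )
  one_edge <- tibble::tibble(
    domain = "http://example.org/C", property = "http://example.org/p",
    range = "http://example.org/D"
  )
  small <- make_graph(no_edges, match_row("x", "instance", score = 1.1))
  large <- make_graph(one_edge, dplyr::bind_rows(
    match_row("x", "instance", score = 1.9),
    match_row("y", "class", score = 1.8)
  ))
  by_score <- rank_query_graphs(list(small, large), mode = "score_sum")
  expect_equal(by_score$graph[[1]]$score, large$score)
  by_size <- rank_query_graphs(list(small, large), mode = "min_subgraph")
  expect_equal(by_size$graph[[1]]$schema_hops, 0L)

  single <- rank_query_graphs(list(small), mode = "score_sum")
  expect_equal(single$rank, 1L)
  expect_error(rank_query_graphs(list()), "no query graphs")

  # total deterministic order, stable across calls
  again <- rank_query_graphs(list(large, small), mode = "score_sum")
  expect_equal(again$canonical, by_score$canonical)
})

test_that("rules trigger on normalized keyword containment", {
  rules <- list(
    list(
      name = "ortholog", trigger_keywords = c("orthologous"),
      head = "?gene1 ?gene2",
      body = "?pair <http://example.org/oma/hasOrtholog> ?gene1 . ?pair <http://example.org/oma/hasOrtholog> ?gene2 ."
    ),
    list(
      name = "paralog", trigger_keywords = c("paralogous"),
      head = "?g", body = "?g <http://example.org/oma/hasParalog> ?h ."
    )
  )
  hit <- triggered_rules("Which genes are orthologous to HBB?", rules)
  expect_equal(length(hit), 1L)
  expect_equal(hit[[1]]$name, "ortholog")
  expect_equal(length(triggered_rules("Which genes are orthologous?", list())), 0L)

  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(rules, path)
  loaded <- read_rules(path)
  expect_equal(length(loaded), 2L)
  expect_equal(
    length(triggered_rules("paralogous genes of HBB", loaded)), 1L
  )
})
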