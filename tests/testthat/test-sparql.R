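fig3_sys <- local({
  suppressMessages(qa_system(build_fixture("fig3_brca")))
})

test_that("emitted queries parse under the strict grammar check", {
  a <- suppressMessages(ask(fig3_sys, "What are the drugs for asthma?", top_k = 5))
  for (q in a$interpretations$sparql) {
    parsed <- parse_sparql(q)
    expect_true(parsed$distinct)
    expect_gt(nrow(parsed$patterns), 0)
    expect_equal(parsed$limit, 1000L)
    expect_true(all(startsWith(parsed$select, "?")))
  }
  expect_error(parse_sparql("ASK { ?s ?p ?o }"), "not a SELECT")
  expect_error(parse_sparql("SELECT ?s WHERE { ?s ?p }"), "cannot parse")
})

test_that("a single-class graph selects all instances of the matched class", {
  a <- suppressMessages(ask(fig3_sys, "list all drugs", top_k = 3))
  top <- a$interpretations[1, ]
  expect_equal(top$graph[[1]]$schema_hops, 0L)
  res <- top$results[[1]]
  expect_equal(nrow(res), 6L) # every drugbank drug
  expect_true(all(grepl("drugbank", res$drugs)))
})

test_that("description matches become word-anchored regex filters", {
  a <- suppressMessages(ask(fig3_sys, "drugs with asthma in the description", top_k = 10))
  descr <- NULL
  for (i in seq_len(nrow(a$interpretations))) {
    g <- a$interpretations$graph[[i]]
    if (any(g$matches$kind == "instance" &
      g$matches$property_iri == "http://purl.org/dc/terms/description")) {
      descr <- a$interpretations[i, ]
      break
    }
  }
  expect_false(is.null(descr))
  expect_match(descr$sparql, "FILTER\\(REGEX")
  expect_match(descr$sparql, "\\\\\\\\basthma")
  # exactly the drug whose description mentions asthma survives the filter
  expect_equal(
    unique(descr$results[[1]]$drugs),
    "http://example.org/drugbank/DB01001"
  )
})

test_that("executing emitted queries equals the independent nested-loop oracle", {
  a <- suppressMessages(ask(fig3_sys, "What are the drugs for asthma?", top_k = 3))
  for (i in seq_len(nrow(a$interpretations))) {
    q <- parse_sparql(a$interpretations$sparql[i])
    got <- match_pattern(fig3_sys$graph, q$patterns)
    want <- oracle_match(fig3_sys$graph, q$patterns)
    expect_equal(
      as.data.frame(got[, sort(names(got))]),
      as.data.frame(want[, sort(names(want))])
    )
  }
})

test_that("the BRCA walkthrough returns the hand-enumerated gene-drug pairs", {
  a <- suppressMessages(ask(
    fig3_sys, "What are the drugs for diseases associated with the BRCA genes?",
    top_k = 10
  ))
  top <- a$interpretations[1, ]
  g <- top$graph[[1]]
  expect_setequal(
    unique(c(g$edges$domain, g$edges$range)),
    c(
      "http://example.org/diseasome/genes", "http://example.org/diseasome/diseases",
      "http://example.org/drugbank/drugs"
    )
  )
  expect_true("http://example.org/diseasome/associatedWith" %in% g$edges$property)
  rows <- top$results[[1]]
  expect_setequal(
    paste(basename(rows$genes), basename(rows$drugs)),
    c("BRCA1 DB00675", "BRCA2 DB00675", "BRCA2 DB00958")
  )
  # an alternative interpretation through the second Drug class is offered
  uses_sider <- vapply(a$interpretations$graph, function(g) {
    "http://example.org/sider/drugs" %in% c(g$edges$domain, g$edges$range, g$matches$node_iri)
  }, TRUE)
  expect_true(any(uses_sider))
  expect_gt(which(uses_sider)[1], 1)
})

test_that("questions with no index hits give a structured no-interpretation outcome", {
  a <- ask(fig3_sys, "enumerate the quasar luminosity function")
  expect_false(a$answered)
  expect_true("quasar" %in% a$unmatched)
  expect_equal(nrow(tidy(a)), 0L)
  expect_equal(glance(a)$n_interpretations, 0L)
})

test_that("top_k caps interpretations and empty result tables are retained", {
  one <- suppressMessages(ask(fig3_sys, "What are the drugs for asthma?", top_k = 1))
  expect_equal(nrow(one$interpretations), 1L)
  several <- suppressMessages(ask(fig3_sys, "What are the drugs for asthma?", top_k = 6))
  expect_lte(nrow(several$interpretations), 6L)
  expect_true(all(several$interpretations$n_results >= 0))
})

test_that("the pipeline is deterministic end to end", {
  q <- "What are the drugs for diseases associated with the BRCA genes?"
  a1 <- suppressMessages(ask(fig3_sys, q))
  a2 <- suppressMessages(ask(fig3_sys, q))
  expect_identical(answer_to_json(a1), answer_to_json(a2))
  sys2 <- suppressMessages(qa_system(build_fixture("fig3_brca")))
  a3 <- suppressMessages(ask(sys2, q))
  expect_identical(answer_to_json(a1), answer_to_json(a3))
})

test_that("optional labels populate human-readable columns and export to CSV", {
  a <- suppressMessages(ask(fig3_sys, "What are the drugs for asthma?", top_k = 1))
  res <- a$interpretations$results[[1]]
  expect_true("drugs_label" %in% names(res))
  expect_true(all(nzchar(res$drugs_label)))
  csv <- answer_results_csv(a)
  expect_match(csv[1], "drugs_label")
  expect_equal(length(csv), nrow(res) + 1L)
})
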