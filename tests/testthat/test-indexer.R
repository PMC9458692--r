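OWL_CLASS <- "http://www.w3.org/2002/07/owl#Class"
RDF_PROPERTY <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#Property"

test_that("index rows have the documented lookup-table shape", {
  g <- build_fixture("fig2_biomed")
  idx <- build_index(g)

  # a side-effect name literal indexed under its instance, class and property
  stroke <- idx[idx$lookup_key == "stroke" &
    idx$uri == "http://example.org/sider/C0038454", ]
  expect_equal(nrow(stroke), 1L)
  expect_equal(stroke$class_iri, "http://example.org/sider/side_effects")
  expect_equal(stroke$property_iri, "http://example.org/sider/sideEffectName")
  expect_gt(stroke$pagerank, 0)

  # both Drug classes are metadata entries under the same key
  drug_meta <- idx[idx$lookup_key == "drug" & idx$class_iri == OWL_CLASS, ]
  expect_setequal(
    drug_meta$uri,
    c("http://example.org/drugbank/drugs", "http://example.org/sider/drugs")
  )

  # a property indexed from its URI fragment with the uri_match sentinel
  pdt <- idx[idx$lookup_key == "possibl diseas target", ]
  expect_equal(pdt$uri, "http://example.org/diseasome/possibleDiseaseTarget")
  expect_equal(pdt$class_iri, RDF_PROPERTY)
  expect_equal(pdt$property_iri, "uri_match")
})

test_that("every entry is grounded in the graph", {
  g <- build_fixture("fig3_brca")
  idx <- build_index(g)
  resources <- unique(c(g$subject, g$object[g$object_kind == "iri"], g$predicate))
  expect_true(all(idx$uri %in% resources))
  # non-sentinel entries are reconstructible: the (uri, property) pair exists
  inst <- idx[idx$property_iri != "uri_match", ]
  pairs_in_graph <- unique(paste(g$subject, g$predicate))
  expect_true(all(paste(inst$uri, inst$property_iri) %in% pairs_in_graph))
  expect_true(all(idx$pagerank >= 0))
})

test_that("index build is idempotent and persists byte-identically", {
  g <- build_fixture("fig2_biomed")
  idx1 <- build_index(g)
  idx2 <- build_index(g)
  p1 <- tempfile()
  p2 <- tempfile()
  write_index(idx1, p1)
  write_index(idx2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  expect_equal(as.data.frame(read_index(p1)), as.data.frame(idx1), tolerance = 1e-12)
})

test_that("incremental append never deletes existing entries", {
  g <- build_fixture("fig2_biomed")
  idx <- build_index(g)
  extra <- kg(tibble::tibble(
    subject = "http://example.org/diseasome/eczema",
    predicate = c(
      "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
      "http://www.w3.org/2000/01/rdf-schema#label"
    ),
    object = c("http://example.org/diseasome/diseases", "eczema"),
    object_kind = c("iri", "literal")
  ))
  bigger <- append_index(idx, extra)
  old_keys <- paste(idx$lookup_key, idx$uri, idx$property_iri)
  new_keys <- paste(bigger$lookup_key, bigger$uri, bigger$property_iri)
  expect_true(all(old_keys %in% new_keys))
  expect_true("eczema" %in% bigger$lookup_key)
})

test_that("untyped instances are skipped with a warning", {
  g <- kg(tibble::tibble(
    subject = c("http://example.org/x", "http://example.org/y"),
    predicate = c(
      "http://www.w3.org/2000/01/rdf-schema#label",
      "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
    ),
    object = c("orphan label", "http://example.org/C"),
    object_kind = c("literal", "iri")
  ))
  expect_warning(idx <- build_index(g), "untyped")
  expect_false("http://example.org/x" %in% idx$uri)
})

test_that("verbose literals are indexed only by their first sentence", {
  long <- paste(
    paste(rep("alpha beta gamma delta", 10), collapse = " "), ". trailing tail"
  )
  g <- kg(dplyr::bind_rows(
    tibble::tibble(
      subject = "http://example.org/i", predicate = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
      object = "http://example.org/C", object_kind = "iri"
    ),
    tibble::tibble(
      subject = "http://example.org/i", predicate = "http://purl.org/dc/terms/description",
      object = long, object_kind = "literal"
    )
  ))
  idx <- build_index(g, index_config(verbose_word_cap = 10, index_uri_fragments = FALSE))
  expect_false(any(grepl("trail", idx$lookup_key)))
  keys <- idx$lookup_key[idx$uri == "http://example.org/i"]
  expect_true(all(lengths(strsplit(keys, " ")) <= 4))
  expect_true("alpha" %in% keys)
})

test_that("nothing to index yields an empty index", {
  g <- kg(tibble::tibble(
    subject = "http://example.org/a",
    predicate = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
    object = "http://example.org/C", object_kind = "iri"
  ))
  idx <- build_index(g, index_config(index_uri_fragments = FALSE))
  expect_equal(nrow(idx), 0L)
})
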