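test_that("equivalent hits group by class and property with member aggregation", {
  idx <- build_index(build_fixture("fig3_brca"))
  entries <- lookup_entries(idx, "brca")
  groups <- group_candidates(entries, "brca")
  labels <- groups[groups$property_iri == "http://www.w3.org/2000/01/rdf-schema#label", ]
  expect_equal(nrow(labels), 1L)
  expect_equal(labels$n_members, 2L)
  expect_setequal(
    labels$members[[1]],
    c("http://example.org/diseasome/BRCA1", "http://example.org/diseasome/BRCA2")
  )
  expect_equal(labels$string_sim, 1 - 1 / 5) # brca vs brca1

  single <- group_candidates(entries[1, ], "brca")
  expect_equal(nrow(single), 1L)
  expect_equal(single$n_members, 1L)
})

test_that("entries under two classes form two candidates", {
  entries <- tibble::tibble(
    lookup_key = "asthma",
    uri = c("http://example.org/diseasome/asthma", "http://example.org/sider/C0004096"),
    class_iri = c("http://example.org/diseasome/diseases", "http://example.org/sider/side_effects"),
    property_iri = c(
      "http://www.w3.org/2000/01/rdf-schema#label",
      "http://example.org/sider/sideEffectName"
    ),
    pagerank = c(0.2, 0.05)
  )
  groups <- group_candidates(entries, "asthma")
  expect_equal(nrow(groups), 2L)
  expect_setequal(groups$kind, "instance")
})

test_that("node centrality breaks string-similarity ties (disease over side effect)", {
  sys <- qa_system(build_fixture("fig1_asthma"))
  entries <- lookup_entries(sys$index, "asthma")
  ranked <- score_candidates(
    group_candidates(entries, "asthma"),
    top_n = 10, max_pagerank = sys$max_pagerank
  )
  disease_rank <- ranked$rank[ranked$node_iri == "http://example.org/diseasome/diseases" &
    ranked$property_iri == "http://www.w3.org/2000/01/rdf-schema#label"]
  se_rank <- ranked$rank[ranked$node_iri == "http://example.org/sider/side_effects"]
  expect_lt(disease_rank, min(se_rank))
  # and the disease's pagerank really is larger despite equal string sim
  expect_equal(length(unique(round(ranked$string_sim, 2))), 1L)
})

test_that("metadata matches outrank instance matches on string-similarity ties", {
  sys <- qa_system(build_fixture("fig2_biomed"))
  ranked <- score_candidates(
    group_candidates(lookup_entries(sys$index, "drug"), "drug"),
    top_n = 10, max_pagerank = sys$max_pagerank
  )
  expect_equal(ranked$kind[1], "class")
  expect_equal(ranked$node_iri[1], "http://example.org/drugbank/drugs")
})

test_that("the semantic gate discards spurious matches and passes OOV words", {
  dir <- tempfile()
  dir.create(dir)
  vec_path <- file.path(dir, "toy.vec")
  writeLines(c(
    "3 4",
    "gene 1 0 0 0",
    "oogenesi 0 1 0 0",
    "genom 0.9 0.1 0 0"
  ), vec_path)
  emb <- read_word_vectors(vec_path)
  expect_equal(embedding_similarity("gene", "oogenesi", emb), 0)
  expect_gt(embedding_similarity("gene", "genom", emb), 0.9)
  expect_true(is.na(embedding_similarity("gene", "unseen", emb)))

  matches <- tibble::tibble(
    token = "gene", kind = "instance",
    class_iri = "http://example.org/C",
    property_iri = "http://www.w3.org/2000/01/rdf-schema#label",
    node_iri = class_iri,
    members = list("http://example.org/i1", "http://example.org/i2", "http://example.org/i3"),
    n_members = 1L,
    matched_key = c("oogenesi", "genom", "unseen"),
    string_sim = c(0.4, 0.5, 0.5), pagerank = 0.1
  )
  kept <- score_candidates(matches, embeddings = emb, semantic_threshold = 0.3, top_n = 5)
  expect_false("oogenesi" %in% kept$matched_key) # cosine 0 < threshold
  expect_true(all(c("genom", "unseen") %in% kept$matched_key))

  # all candidates filtered -> empty list, token becomes unconstrained
  none <- score_candidates(matches[1, ], embeddings = emb, semantic_threshold = 0.3, top_n = 5)
  expect_equal(nrow(none), 0L)
})

test_that("top-n bounds candidates per token and a single survivor keeps rank 1", {
  sys <- qa_system(build_fixture("fig2_biomed"))
  for (key in c("asthma", "drug", "diseas")) {
    ranked <- score_candidates(
      group_candidates(lookup_entries(sys$index, key), key),
      top_n = 2, max_pagerank = sys$max_pagerank
    )
    expect_lte(nrow(ranked), 2L)
  }
  one <- score_candidates(
    group_candidates(lookup_entries(sys$index, "ibuprofen"), "ibuprofen")[1, ],
    top_n = 3, max_pagerank = sys$max_pagerank
  )
  expect_equal(one$rank, 1L)
})

test_that("disabling node centrality flips the top candidate on the acronym decoy", {
  sys <- qa_system(build_fixture("cordis_decoy"))
  groups <- group_candidates(lookup_entries(sys$index, "topic"), "topic")
  with_pr <- score_candidates(groups, top_n = 5, use_pagerank = TRUE, max_pagerank = sys$max_pagerank)
  without <- score_candidates(groups, top_n = 5, use_pagerank = FALSE, max_pagerank = sys$max_pagerank)
  expect_equal(with_pr$kind[1], "class")
  expect_equal(with_pr$node_iri[1], "http://example.org/cordis/topics")
  expect_equal(without$kind[1], "instance")
  expect_false(identical(with_pr$node_iri[1], without$node_iri[1]))
})
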