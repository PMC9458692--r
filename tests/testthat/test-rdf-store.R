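test_that("duplicate triples across files collapse under set semantics", {
  ttl <- "@prefix ex: <http://example.org/> .\nex:a ex:p ex:b ."
  f1 <- write_temp_ttl(ttl)
  f2 <- write_temp_ttl(ttl)
  g <- read_kg(c(f1, f2))
  expect_equal(nrow(g), 1L)
  expect_equal(g$subject, "http://example.org/a")
})

test_that("turtle reader handles prefixes, lists, literals and blank nodes", {
  g <- read_kg(write_temp_ttl(fig_ttl_text()))
  expect_equal(nrow(g), 6L)
  lab <- g[g$predicate == "http://www.w3.org/2000/01/rdf-schema#label", ]
  expect_setequal(lab$object, c("migraine", "Ibuprofen"))
  expect_equal(sort(lab$lang, na.last = TRUE), c("en", NA))
  w <- g[endsWith(g$predicate, "weight"), ]
  expect_equal(w$object, "206.29")
  expect_equal(w$datatype, "http://www.w3.org/2001/XMLSchema#decimal")

  bn <- read_kg(write_temp_ttl(paste(
    "@prefix ex: <http://example.org/> .",
    "_:x ex:p ex:b .",
    "ex:c ex:q [ ex:r ex:d ] .",
    sep = "\n"
  )))
  expect_true(all(bn$subject != "")) # skolemized, no blank labels left
  expect_true(any(startsWith(bn$subject, "urn:skolem:")))
  expect_true(any(startsWith(bn$object[bn$object_kind == "iri"], "urn:skolem:")))
})

test_that("malformed turtle raises a parse error naming the file", {
  path <- write_temp_ttl("@prefix ex: <http://example.org/> .\nex:a ex:p .")
  expect_error(read_kg(path), basename(path))
  expect_error(read_kg(character(0)), "empty input")
  expect_error(read_kg("/nonexistent/file.ttl"), "not found")
})

test_that("fixture class count matches a direct rdf:type scan", {
  g <- build_fixture("fig2_biomed")
  direct <- sort(unique(g$object[
    g$predicate == "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  ]))
  expect_equal(kg_classes(g)$class_iri, direct)
  expect_equal(length(direct), 7L)
})

test_that("N-Triples round trip preserves the triple set exactly", {
  for (fx in c("fig1_asthma", "fig2_biomed", "cordis_decoy")) {
    g <- build_fixture(fx)
    path <- tempfile(fileext = ".nt")
    write_ntriples(g, path)
    g2 <- read_kg(path, format = "ntriples")
    expect_identical(write_ntriples(g), write_ntriples(g2))
  }
})

test_that("RDF/XML reader agrees with the equivalent Turtle", {
  xml <- paste(
    "<?xml version=\"1.0\"?>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "         xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
    "         xmlns:ds=\"http://example.org/diseasome/\">",
    "  <ds:diseases rdf:about=\"http://example.org/diseasome/migraine\">",
    "    <rdfs:label>migraine</rdfs:label>",
    "    <ds:possibleDrug rdf:resource=\"http://example.org/drugbank/DB01050\"/>",
    "  </ds:diseases>",
    "</rdf:RDF>",
    sep = "\n"
  )
  ttl <- paste(
    "@prefix ds: <http://example.org/diseasome/> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "ds:migraine a ds:diseases ; rdfs:label \"migraine\" ;",
    "  ds:possibleDrug <http://example.org/drugbank/DB01050> .",
    sep = "\n"
  )
  gx <- read_kg(write_temp_ttl(xml, ".rdf"))
  gt <- read_kg(write_temp_ttl(ttl))
  expect_identical(write_ntriples(gx), write_ntriples(gt))
})

test_that("match_pattern handles the worked examples", {
  g <- build_fixture("fig2_biomed")
  type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  drugs <- match_pattern(g, bgp(c("?d", type, "http://example.org/sider/drugs")))
  expect_equal(nrow(drugs), 2L)

  empty <- kg()
  expect_equal(nrow(match_pattern(empty, bgp(c("?s", "?p", "?o")))), 0L)

  expect_error(match_pattern(g, bgp()), "empty pattern")
  bad <- tibble::tibble(subject = "?s", predicate = NA_character_, object = "?o")
  expect_error(match_pattern(g, bad), "non-empty")
})

test_that("the four-pattern BRCA join equals the hand-enumerated pairing", {
  g <- build_fixture("fig3_brca")
  ds <- function(x) paste0("http://example.org/diseasome/", x)
  type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  rows <- match_pattern(g, bgp(
    c("?gene", type, ds("genes")),
    c("?gene", ds("associatedWith"), "?disease"),
    c("?disease", ds("possibleDrug"), "?drug"),
    c("?gene", "http://www.w3.org/2000/01/rdf-schema#label", "?label")
  ))
  brca <- rows[startsWith(rows$label, "\"BRCA"), ]
  expect_equal(
    sort(paste(basename(brca$gene), basename(brca$drug))),
    c("BRCA1 DB00675", "BRCA2 DB00675", "BRCA2 DB00958")
  )
})

test_that("match_pattern equals an exhaustive backtracking join on random graphs", {
  type <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  ns <- "http://example.org/rand/"
  for (seed in 1:8) {
    g <- random_kg(seed = seed, n_instances = 25L)
    expect_lte(nrow(g), 200L)
    patterns <- list(
      bgp(c("?s", "?p", "?o")),
      bgp(c("?s", type, "?c"), c("?s", "?p", "?o")),
      bgp(
        c("?a", paste0(ns, "prop1"), "?b"),
        c("?b", type, "?c"), c("?a", type, "?d")
      ),
      bgp(
        c("?a", "?p", "?b"), c("?b", "?q", "?c"),
        c("?c", type, paste0(ns, "Class1"))
      ),
      bgp(c("?x", "?p", "?x"))
    )
    for (pat in patterns) {
      got <- match_pattern(g, pat)
      want <- oracle_match(g, pat)
      expect_equal(
        as.data.frame(got[, sort(names(got))]),
        as.data.frame(want[, sort(names(want))])
      )
    }
  }
})
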