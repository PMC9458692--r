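Package: kgask
Title: Natural-Language Question Answering over RDF Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A training-data-free engine that translates English questions
    into ranked SPARQL queries over RDF knowledge graphs. It builds a
    PageRank-scored inverted index over literals and URI fragments, derives a
    class-level schema multigraph from instance triples, segments questions by
    longest-match lookup, groups and ranks candidate matches by string
    similarity, optional word-embedding similarity and node centrality,
    connects one candidate per token through approximate Steiner trees on the
    schema graph, and serializes the ranked query graphs to executable SPARQL
    SELECT queries. Includes a small RDF store with Turtle, N-Triples and
    RDF/XML readers and a basic-graph-pattern evaluator, plus fixture
    generators for biomedical toy knowledge graphs (drugs, diseases, side
    effects, genes, gene expression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
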