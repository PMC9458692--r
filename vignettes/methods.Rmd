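---
title: "From English questions to ranked SPARQL: the kgask method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From English questions to ranked SPARQL: the kgask method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgask)
```

## The problem and the model

Given an RDF knowledge graph whose instances carry explicit `rdf:type`
assertions, `kgask` translates an English question into a ranked list of
SPARQL SELECT queries, each a complete, executable interpretation of the
question. No question–answer training pairs are needed; everything the
ranker uses is computed from the graph itself. The assumptions are:

* every instance that should be findable has at least one `rdf:type`
  (resources without a class cannot be attached to the schema graph and are
  skipped with a diagnostic);
* labels and other searchable literals, or failing that URI local names,
  carry meaningful words;
* when several datasets are loaded together they share classes, so their
  inferred schemas join into one connected graph.

The pipeline has two phases. Preprocessing builds (i) an inverted index from
normalized keyword n-grams to `(uri, class, property, pagerank)` entries and
(ii) a class-level schema multigraph inferred from instance triples. At
question time, tokens are matched against the index, grouped into candidate
matches, connected through the schema by approximate Steiner trees, and the
resulting query graphs are ranked and serialized to SPARQL.

```{r pipeline}
system <- qa_system(build_fixture("fig2_biomed"))
answer <- ask(system, "What are the drugs for asthma?")
tidy(answer)
```

## Why centrality enters the ranking

String similarity alone cannot decide whether "asthma" means the *Disease*
instance or the *Side-Effect* instance that carries the identical term, nor
whether "topic" means the Topic class or a project whose acronym happens to
be "Topic". PageRank over the resource graph (one directed edge per triple
with an IRI object, literals excluded) acts as a data-driven prior: nodes
that many triples point at — central classes, frequently-targeted disease
instances — outrank accidental string twins. Because `rdf:type` edges count,
class metadata entries systematically outrank instance matches when string
similarity ties, which is what makes "drug" resolve to the Drug class rather
than to some instance that mentions the word.

The per-candidate score is

```
score = round(string_sim, 2) + pagerank / max(pagerank)        (centrality on)
score = round(string_sim, 2)                                   (ablation)
```

A numeric (rather than purely lexicographic) combination is required because
the query-graph ranking sums the scores of the matches a graph covers;
rounding the Levenshtein ratio to two decimals makes centrality the
tie-breaker for effectively-equal string matches while never letting a weak
string match with a huge hub score displace an exact one by more than one
similarity unit. Remaining ties break on `(class_iri, property_iri)` so the
ordering is total and reproducible. String similarity is measured against
the matched lookup key; with exact-key retrieval it is 1 unless prefix
retrieval fired (e.g. token "brca" against key "brca1", similarity 0.8).

Ranking whole interpretations follows the same logic: the default
`score_sum` mode returns the graph maximizing the sum of covered match
scores, with fewer hops and canonical text as tie-breaks. The `min_subgraph`
mode — fewest schema edges first, then total hops, then string-similarity
sum — exists as the ablation baseline; on the bundled decoy fixtures it
prefers the drug whose *description* mentions "asthma" (a 0-schema-edge
graph) and the project whose *acronym* is "Topic", which is precisely the
failure mode score-sum ranking avoids.

## Hop counting

A query graph's `hop_count` is the number of property edges it will emit as
triple patterns: schema relation edges plus one attribute edge per
instance-literal match (the `?disease rdfs:label ?v` pattern that carries
the filter). Under this convention "drugs for asthma" is a 2-hop graph
(Drug—possibleDiseaseTarget→Disease plus the label edge) while the
description decoy is 1-hop, matching how the two interpretations differ in
practice. `schema_hops` (relation edges only) is kept separately and drives
the `min_subgraph` ablation order.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `index.max_ngram_len` | 4 words | longest lookup key stored; covers multi-word property names like "possible disease target" |
| `index.verbose_word_cap` | 30 words | literals longer than this are indexed by their first sentence only |
| `index.index_uri_fragments` | TRUE | split camel-case/punctuated local names into keywords |
| `top_n` | 3 | candidates kept per token; bounds combinations by `top_n^T` |
| `semantic_threshold` | 0.3 cosine | word-embedding gate; out-of-vocabulary words pass |
| `use_pagerank` | TRUE | FALSE gives the string-similarity-only ablation |
| `mode` | `score_sum` | interpretation ranking; `min_subgraph` is the ablation |
| `max_combinations` | 64 | cap on candidate combinations explored best-first |
| `variant_cap` | 16 | property variants enumerated per equal-cost tree |
| `top_k` | 5 | interpretations returned |
| `result_limit` | 1000 | LIMIT on every emitted query |

Stopwords (including interrogative scaffolding such as "what", "which",
"show", and the use/used family from classic IR stopword lists) are removed
from questions only, never from index keys, so inner words of multi-word
keys survive. Both sides share one normalization: lowercase, punctuation and
camel-case splitting, Porter stemming. The full Porter algorithm is
reproduced deliberately, including its known quirks — "gaseous" does not
stem to "gas", so that question would fail on a graph indexed under "gas",
exactly the behaviour a practitioner should expect from this family of
pipelines.

## Numerical and structural choices

* **PageRank** is computed by power iteration with damping 0.85, an L1
  tolerance of 1e-12 and a 1000-iteration cap (an error reports the residual
  on non-convergence); dangling mass is redistributed uniformly. Tests
  cross-check against an independent implementation (igraph's PRPACK) to
  1e-8 and verify that scores sum to one.
* **Steiner approximation**: metric closure over the terminal classes via
  shortest paths, minimum spanning tree of the closure, expansion back to
  graph edges, iterative pruning of non-terminal leaves. On tree-shaped
  schemas this is exact; on general multigraphs it is within the classical
  factor-2 bound, both asserted against exhaustive search on small graphs.
* **Property matches** ("possible disease target") force their schema edge
  into the tree. A property that only ever links a class to literals (a
  description attribute) instead anchors to its domain class — preferring a
  class another token already touches — and contributes a projected value
  pattern; this is what lets "genes with lung in the description" reach the
  description attribute at all.
* **Ties everywhere** break on canonical serializations (sorted edge and
  match descriptors), making the whole pipeline byte-deterministic for a
  fixed graph, configuration and question.
* **Blank nodes** are skolemized on load into stable IRIs derived from the
  file name and label, so indexing and schema extraction treat them like any
  resource. **Degenerate inputs**: empty pattern lists, empty questions,
  tokens with no surviving candidate (the token becomes unconstrained),
  all-filtered candidate lists, and disconnected combinations all have
  defined, tested outcomes rather than errors.
* The **index persists** to a single sorted TSV, so rebuilding an unchanged
  graph is byte-identical and appends never delete existing entries.

## What the fixtures emulate — and what they do not

The bundled fixtures are synthetic miniatures of the integrated biomedical
setting the method targets: two Drug classes in different namespaces bridged
by `sameAs`, inverse (`possibleDiseaseTarget`/`possibleDrug`) and disjoint
(`isExpressedIn`/`isAbsentIn`) property pairs, identical terms naming both a
Disease and a Side-Effect, a drug description containing a disease keyword,
and an acronym that collides with a class name. The randomized generator
adds seeded graphs with controllable untyped-instance and verbose-literal
injection for property-style tests.

Passing on these fixtures demonstrates the mechanics — tokenization,
grouping, centrality tie-breaking, Steiner connectivity, variant
enumeration, ranking directions — at desk scale. It does not demonstrate
recall on real releases of Drugbank/Sider/Diseasome-scale data (millions of
triples, noisy labels, richer ambiguity), nor benchmark F1 against other
systems; those require the original datasets and are out of scope here.
Test problem sizes were chosen to keep the whole suite in the order of a
minute: random graphs of ≤ 200 triples for the schema and join oracles,
≤ 100 resource nodes for the PageRank oracle, ≤ 8-node schemas with 100
seeded instances for the Steiner bound.

## Known limitations

Aggregations and counting questions, superlatives/comparatives, conjunctive
questions binding several instances of one class, and ASK (boolean)
questions are out of scope of the query-graph construction; properties whose
domain equals their range (symmetric relations such as orthology) are only
reachable through custom rewrite rules, registered as keyword-triggered
subquery blocks. The index performs no synonym expansion: questions must use
the graph's own vocabulary. Candidate ranking can still be wrong when an
exact string match on a peripheral entity competes with the intended match
of a slightly different surface form — the ranked interpretation list, JSON
explanation records and per-stage diagnostics exist precisely so a user can
recognize and correct such cases.
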