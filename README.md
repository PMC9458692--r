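# kgask

Natural-language question answering over RDF knowledge graphs, without
training data.

Domain scientists increasingly publish data as RDF knowledge graphs — drugs,
diseases, side effects, genes and where they are expressed — but querying
them requires SPARQL and an intimate knowledge of each data model. Systems
learned from question–answer pairs do not transfer to scientific graphs,
where no such training corpora exist. `kgask` is for the bioinformatician or
data steward who wants an English question answered with a **ranked list of
executable SPARQL interpretations**, each one inspectable and explainable,
over any reasonably-typed RDF dataset.

## The method

**Preprocessing** (once per graph):

* An **inverted index** maps every normalized keyword *n*-gram (lowercased,
  punctuation/camel-case split, Porter-stemmed) of the indexed literals and
  URI fragments to the entry `(lookup key, URI, class, property, PageRank)`.
  Classes and properties themselves are indexed as metadata entries, so
  `possibleDiseaseTarget` is findable as "possible disease target".
* **PageRank** over the directed resource graph (one edge per triple with an
  IRI object) scores each node's centrality. Because `rdf:type` edges feed
  class nodes, frequently-instantiated classes score high — a proxy for
  "common-sense" importance: *asthma* is more commonly a Disease than a
  Side-Effect.
* A **schema graph** is inferred from instance data: each triple
  (s, p, o) contributes the class-level edge type(s) —p→ type(o), yielding an
  accurate, possibly multigraph schema even when `rdfs:domain`/`rdfs:range`
  are missing, and joining several datasets that share classes.

**Per question:**

1. **Tokenize** by greedy longest match against the index keys.
2. **Group and rank candidates** per token by `(class, property)`; the score
   is `round(string_sim, 2) + pagerank / max(pagerank)`, with an optional
   word-embedding cosine gate that discards semantically spurious matches
   (*gene* vs *oogenesis*). At most `top_n` candidates survive per token, so
   at most `top_n^T` combinations exist for `T` tokens.
3. **Build query graphs**: for each combination of one candidate per token,
   attach the candidates to their schema classes and connect them with an
   approximate **Steiner tree** (shortest-path metric closure → MST →
   expansion → pruning; optimal on tree schemas, ≤ 2× optimal in general).
   When two classes are joined by several properties (`isExpressedIn` vs
   `isAbsentIn`), one query graph is emitted per property variant — equal
   shapes can have opposite meanings.
4. **Rank interpretations** by the **sum of covered match scores** (not by
   minimal size: the smallest subgraph for "drugs for asthma" is the drug
   whose *description* mentions asthma — precise but nearly answerless).
   The ablation mode `min_subgraph` with `use_pagerank = FALSE` reproduces
   the classical string-similarity/minimal-subgraph ranking.
5. **Emit and execute SPARQL** with meaningful variable names, word-anchored
   case-insensitive regex filters for instance matches (so "BRCA" retrieves
   BRCA1 and BRCA2), optional `rdfs:label` columns, and custom keyword-
   triggered rewrite rules as subquery blocks.

## Worked example

```r
library(kgask)

graph  <- build_fixture("fig3_brca")   # drugs, diseases, genes, side effects
system <- qa_system(graph)
answer <- ask(system, "What are the drugs for diseases associated with the BRCA genes?",
              top_k = 3)
answer
```

```
# Question: What are the drugs for diseases associated with the BRCA genes?
Tokens: drug | diseas | associ | brca | gene
3 interpretation(s), mode score_sum
Top (score 7.309, 3 hops, 3 rows):
SELECT DISTINCT ?diseases ?genes ?drugs ?genes_label ?diseases_label ?drugs_label
WHERE {
  ?diseases <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://example.org/diseasome/diseases> .
  ?genes <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://example.org/diseasome/genes> .
  ?drugs <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://example.org/drugbank/drugs> .
  ?diseases <http://example.org/diseasome/possibleDrug> ?drugs .
  ?genes <http://example.org/diseasome/associatedWith> ?diseases .
  ?genes <http://www.w3.org/2000/01/rdf-schema#label> ?genes_label .
  FILTER(REGEX(STR(?genes_label), "\\bbrca", "i"))
  OPTIONAL { ?diseases <http://www.w3.org/2000/01/rdf-schema#label> ?diseases_label . }
  OPTIONAL { ?drugs <http://www.w3.org/2000/01/rdf-schema#label> ?drugs_label . }
}
LIMIT 1000

# A tibble: 3 × 6
  diseases                    genes drugs genes_label diseases_label drugs_label
1 http://example.org/diseaso… http… http… BRCA1       breast cancer  Tamoxifen
2 http://example.org/diseaso… http… http… BRCA2       breast cancer  Tamoxifen
3 http://example.org/diseaso… http… http… BRCA2       ovarian cancer Carboplatin
```

The five question tokens were linked to the two metadata classes, the
`associatedWith` property, the grouped BRCA1/BRCA2 gene instances, and the
gene class; the top query graph joins Genes–Disease–Drug with the gene label
filtered to `\bbrca`. Each returned row pairs a BRCA gene with a drug for
one of its associated cancers. `tidy(answer)` gives the interpretation table
(rank, score, hops, SPARQL), `glance(answer)` the pipeline counters — for
this question, 24 candidate combinations were enumerated (bounded by
`top_n^tokens = 3^5`) producing 16 distinct query graphs — and
`autoplot(answer)` a score-by-rank chart. A thin command line lives at
`inst/cli/kgask` (`index`, `schema`, `ask`, `fixtures build`).

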