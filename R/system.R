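#' System configuration
#'
#' All tunables of the question-answering pipeline in one validated list.
#' Every knob has a documented default; unknown keys are an error naming the
#' key. Serializes round-trip-stable to YAML.
#'
#' @param data_paths RDF input files (used by [index_system()]).
#' @param index An [index_config()] (or a list of its fields from YAML).
#' @param top_n Candidates kept per token (bounds combinations by
#'   `top_n ^ n_tokens`).
#' @param semantic_threshold Word-embedding cosine gate for candidates.
#' @param use_pagerank `FALSE` switches to the string-similarity-only
#'   ablation ranking.
#' @param mode Query-graph ranking mode, `"score_sum"` or `"min_subgraph"`.
#' @param max_combinations Candidate-combination cap.
#' @param variant_cap Property-variant cap per combination.
#' @param top_k Interpretations returned per question.
#' @param result_limit LIMIT applied to every emitted query.
#' @param embeddings_path Optional word2vec text-format vector file.
#' @param rules_path Optional YAML rules file.
#' @param seed Seed recorded for reproducibility of randomized fixtures.
#' @return A list of class `kg_config`.
#' @export
qa_config <- function(data_paths = character(0),
                      index = index_config(),
                      top_n = 3L,
                      semantic_threshold = 0.3,
                      use_pagerank = TRUE,
                      mode = c("score_sum", "min_subgraph"),
                      max_combinations = 64L,
                      variant_cap = 16L,
                      top_k = 5L,
                      result_limit = 1000L,
                      embeddings_path = NULL,
                      rules_path = NULL,
                      seed = 1L) {
  mode <- match.arg(mode)
  if (is.list(index) && !inherits(index, "kg_index_config")) {
    index <- do.call(index_config, index)
  }
  stopifnot(
    top_n >= 1, top_k >= 1, max_combinations >= 1, variant_cap >= 1,
    result_limit >= 1, semantic_threshold >= -1, semantic_threshold <= 1
  )
  structure(
    list(
      data_paths = data_paths, index = index, top_n = as.integer(top_n),
      semantic_threshold = semantic_threshold,
      use_pagerank = isTRUE(use_pagerank), mode = mode,
      max_combinations = as.integer(max_combinations),
      variant_cap = as.integer(variant_cap), top_k = as.integer(top_k),
      result_limit = as.integer(result_limit),
      embeddings_path = embeddings_path, rules_path = rules_path,
      seed = as.integer(seed)
    ),
    class = "kg_config"
  )
}

#' Load a configuration from YAML
#'
#' @param path YAML file whose keys are [qa_config()] arguments (the `index`
#'   key holds [index_config()] arguments). Unknown keys are an error.
#' @return A `kg_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(qa_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("read_config(): unknown configuration key(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(raw$index)) {
    unknown <- setdiff(names(raw$index), names(formals(index_config)))
    if (length(unknown) > 0) {
      stop("read_config(): unknown index configuration key(s): ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
  }
  do.call(qa_config, raw)
}

#' Prepare a question-answering system over a knowledge graph
#'
#' The preprocessing phase, run once per graph: PageRank scores, the
#' inverted index, and the instance-derived schema graph.
#'
#' @param graph A [kg()] object (or character paths, read via [read_kg()]).
#' @param config A [qa_config()].
#' @return A `kg_system` list: `graph`, `index`, `schema`, `pagerank`,
#'   `embeddings`, `rules`, `config`, `max_pagerank`.
#' @export
qa_system <- function(graph, config = qa_config()) {
  if (is.character(graph)) graph <- read_kg(graph)
  pagerank <- pagerank_scores(graph)
  index <- build_index(graph, config$index, scores = pagerank)
  schema <- extract_schema(graph)
  embeddings <- if (!is.null(config$embeddings_path)) {
    read_word_vectors(config$embeddings_path)
  }
  rules <- if (!is.null(config$rules_path)) read_rules(config$rules_path) else list()
  structure(
    list(
      graph = graph, index = index, schema = schema, pagerank = pagerank,
      embeddings = embeddings, rules = rules, config = config,
      max_pagerank = if (nrow(index) > 0) max(index$pagerank) else 1
    ),
    class = "kg_system"
  )
}

#' @export
print.kg_system <- function(x, ...) {
  cat("# QA system: ", nrow(x$graph), " triples, ", nrow(x$index),
    " index entries, ", nrow(x$schema$nodes), " schema classes\n",
    sep = ""
  )
  invisible(x)
}

#' Answer a natural-language question
#'
#' The full translation pipeline: longest-match tokenization against the
#' inverted index, candidate grouping/scoring per token, query-graph
#' construction over the schema, graph ranking, SPARQL generation and
#' execution. A ranked list of interpretations is returned rather than a
#' single answer; interpretations with empty result tables are retained.
#'
#' @param system A [qa_system()].
#' @param question Question text.
#' @param top_k Interpretations to return (default from the config).
#' @param mode Ranking mode override (`"score_sum"` / `"min_subgraph"`).
#' @param use_pagerank Ablation override of the config flag.
#' @return A `kg_answer` object. When no token matches the index, the
#'   answer has `answered = FALSE` and carries the unmatched words.
#' @export
ask <- function(system, question, top_k = NULL, mode = NULL, use_pagerank = NULL) {
  stopifnot(inherits(system, "kg_system"))
  cfg <- system$config
  top_k <- top_k %||% cfg$top_k
  mode <- mode %||% cfg$mode
  use_pagerank <- use_pagerank %||% cfg$use_pagerank
  tokens <- tokenize_question(system$index, question, stopwords = cfg$index$stopwords)
  no_answer <- function(reason) {
    structure(
      list(
        question = question, answered = FALSE, reason = reason,
        tokens = tokens, unmatched = attr(tokens, "unmatched"),
        candidates = list(),
        interpretations = tibble::tibble(),
        n_combinations = 0L, n_graphs = 0L, mode = mode
      ),
      class = "kg_answer"
    )
  }
  if (nrow(tokens) == 0) {
    return(no_answer("no token matches the index"))
  }
  candidates <- lapply(seq_len(nrow(tokens)), function(i) {
    score_candidates(
      group_candidates(tokens$entries[[i]], tokens$token[i]),
      embeddings = system$embeddings,
      semantic_threshold = cfg$semantic_threshold,
      top_n = cfg$top_n,
      use_pagerank = use_pagerank,
      max_pagerank = system$max_pagerank
    )
  })
  names(candidates) <- tokens$token
  graphs <- build_query_graphs(
    system$schema, candidates,
    max_combinations = cfg$max_combinations, variant_cap = cfg$variant_cap
  )
  if (length(graphs) == 0) {
    return(no_answer("no connected query graph covers the matched tokens"))
  }
  ranked <- rank_query_graphs(graphs, mode = mode)
  ranked <- utils::head(ranked, top_k)
  rules <- triggered_rules(question, system$rules, stopwords = cfg$index$stopwords)
  sparql <- vapply(
    ranked$graph,
    function(g) graph_to_sparql(g, rules = rules, limit = cfg$result_limit), ""
  )
  results <- lapply(sparql, function(q) run_sparql(system$graph, q))
  structure(
    list(
      question = question, answered = TRUE, reason = NULL,
      tokens = tokens, unmatched = attr(tokens, "unmatched"),
      candidates = candidates,
      interpretations = tibble::tibble(
        rank = ranked$rank, score = ranked$score,
        hop_count = ranked$hop_count, schema_hops = ranked$schema_hops,
        sparql = sparql, n_results = vapply(results, nrow, 0L),
        results = results, graph = ranked$graph
      ),
      rules = rules,
      n_combinations = attr(graphs, "n_combinations"),
      n_graphs = length(graphs), mode = mode
    ),
    class = "kg_answer"
  )
}

#' @export
print.kg_answer <- function(x, ...) {
  cat("# Question: ", x$question, "\n", sep = "")
  if (!x$answered) {
    cat(
      "No interpretation (", x$reason, "); unmatched words: ",
      paste(x$unmatched, collapse = ", "), "\n",
      sep = ""
    )
    return(invisible(x))
  }
  cat(
    "Tokens: ", paste(x$tokens$token, collapse = " | "),
    if (length(x$unmatched) > 0) {
      paste0("   (skipped: ", paste(x$unmatched, collapse = ", "), ")")
    },
    "\n",
    sep = ""
  )
  cat(nrow(x$interpretations), " interpretation(s), mode ", x$mode, "\n", sep = "")
  top <- x$interpretations[1, ]
  cat(
    "Top (score ", round(top$score, 3), ", ", top$hop_count, " hops, ",
    top$n_results, " rows):\n", top$sparql, "\n",
    sep = ""
  )
  print(top$results[[1]])
  invisible(x)
}

#' Results of an interpretation as CSV text
#'
#' @param answer A `kg_answer`.
#' @param rank Which interpretation.
#' @param path Optional output file.
#' @return CSV lines, invisibly.
#' @export
answer_results_csv <- function(answer, rank = 1L, path = NULL) {
  stopifnot(answer$answered, rank <= nrow(answer$interpretations))
  df <- answer$interpretations$results[[rank]]
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Run the preprocessing phase and persist its artifacts
#'
#' Builds the index and schema for the configured data files and writes
#' them (index TSV, schema N-Triples, PageRank TSV, summary YAML) to a
#' directory; re-running on unchanged input writes identical artifacts.
#'
#' @param config A [qa_config()] with `data_paths` set.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the artifact paths and summary counts.
#' @export
index_system <- function(config, out_dir) {
  if (length(config$data_paths) == 0) {
    stop("index_system(): no data_paths configured", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  system <- qa_system(read_kg(config$data_paths), config)
  paths <- list(
    index = file.path(out_dir, "index.tsv"),
    schema = file.path(out_dir, "schema.nt"),
    pagerank = file.path(out_dir, "pagerank.tsv"),
    summary = file.path(out_dir, "summary.yaml")
  )
  write_index(system$index, paths$index)
  writeLines(write_schema_ntriples(system$schema), paths$schema)
  utils::write.table(
    as.data.frame(system$pagerank),
    paths$pagerank,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  summary <- list(
    n_triples = nrow(system$graph),
    n_index_entries = nrow(system$index),
    n_classes = nrow(system$schema$nodes),
    n_schema_edges = nrow(system$schema$edges),
    pagerank_iterations = attr(system$pagerank, "iterations")
  )
  yaml::write_yaml(summary, paths$summary)
  invisible(list(paths = paths, counts = summary))
}

#' Render an answer as a JSON explanation record
#'
#' Structured per-stage record (tokens found, candidates kept, combinations
#' tried, ranked interpretations with SPARQL and results) — the scriptable
#' stand-in for an interactive disambiguation dialog. Byte-identical for
#' identical inputs.
#'
#' @param answer A `kg_answer`.
#' @param path Optional output file.
#' @return JSON string, invisibly.
#' @export
answer_to_json <- function(answer, path = NULL) {
  payload <- list(
    question = answer$question,
    answered = answer$answered,
    mode = answer$mode,
    tokens = answer$tokens$token,
    unmatched = answer$unmatched,
    candidates = lapply(answer$candidates, function(m) {
      m$members <- vapply(m$members, paste, "", collapse = " ")
      m[, c(
        "rank", "kind", "node_iri", "property_iri", "matched_key",
        "string_sim", "pagerank", "score", "members"
      )]
    }),
    n_combinations = answer$n_combinations,
    n_graphs = answer$n_graphs,
    interpretations = if (answer$answered) {
      lapply(seq_len(nrow(answer$interpretations)), function(i) {
        row <- answer$interpretations[i, ]
        list(
          rank = row$rank, score = row$score, hop_count = row$hop_count,
          schema_hops = row$schema_hops, sparql = row$sparql,
          n_results = row$n_results, results = row$results[[1]]
        )
      })
    } else {
      list()
    }
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}
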