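#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ranked answer into its interpretation table
#'
#' @param x A `kg_answer` from [ask()].
#' @param ... Unused.
#' @return A tibble with one row per interpretation: `rank`, `score`,
#'   `hop_count`, `schema_hops`, `n_results`, `sparql`.
#' @export
tidy.kg_answer <- function(x, ...) {
  if (!x$answered) {
    return(tibble::tibble(
      rank = integer(0), score = numeric(0), hop_count = integer(0),
      schema_hops = integer(0), n_results = integer(0), sparql = character(0)
    ))
  }
  x$interpretations[, c("rank", "score", "hop_count", "schema_hops", "n_results", "sparql")]
}

#' One-row summary of an answer
#'
#' @param x A `kg_answer`.
#' @param ... Unused.
#' @return Tibble: `answered`, `n_tokens`, `n_combinations`, `n_graphs`,
#'   `n_interpretations`, `mode`.
#' @export
glance.kg_answer <- function(x, ...) {
  tibble::tibble(
    answered = x$answered,
    n_tokens = nrow(x$tokens),
    n_combinations = x$n_combinations,
    n_graphs = x$n_graphs,
    n_interpretations = if (x$answered) nrow(x$interpretations) else 0L,
    mode = x$mode
  )
}

#' Tidy an inverted index
#'
#' @param x A `kg_index`.
#' @param ... Unused.
#' @return The entry table as a plain tibble.
#' @export
tidy.kg_index <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of an inverted index
#'
#' @param x A `kg_index`.
#' @param ... Unused.
#' @return Tibble with entry/key/resource counts and the PageRank range.
#' @export
glance.kg_index <- function(x, ...) {
  tibble::tibble(
    n_entries = nrow(x),
    n_keys = dplyr::n_distinct(x$lookup_key),
    n_resources = dplyr::n_distinct(x$uri),
    n_metadata = sum(x$class_iri %in% c(OWL_CLASS, RDF_PROPERTY)),
    max_pagerank = if (nrow(x) > 0) max(x$pagerank) else NA_real_
  )
}

#' Plot interpretation scores of an answer
#'
#' Bar chart of interpretation scores by rank, annotated with hop counts.
#'
#' @param object A `kg_answer`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kg_answer <- function(object, ...) {
  stopifnot(object$answered)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$rank), y = .data$score, fill = factor(.data$hop_count)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "interpretation rank", y = "score (sum of match scores)",
      fill = "hops", title = object$question
    ) +
    ggplot2::theme_minimal()
}

#' Plot a schema graph
#'
#' Class nodes on a deterministic circular layout with one labelled segment
#' per property edge.
#'
#' @param object A `kg_schema`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kg_schema <- function(object, ...) {
  rel <- schema_relations(object)
  nodes <- sort(unique(c(object$nodes$class_iri, rel$domain, rel$range)))
  angle <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  layout <- tibble::tibble(
    class_iri = nodes, x = cos(angle), y = sin(angle),
    name = iri_local_name(nodes)
  )
  edges <- rel |>
    dplyr::left_join(layout, by = c(domain = "class_iri")) |>
    dplyr::left_join(layout, by = c(range = "class_iri"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to),
      colour = "grey60",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) +
    ggplot2::geom_text(
      data = edges,
      ggplot2::aes(
        x = (.data$x + .data$x_to) / 2, y = (.data$y + .data$y_to) / 2,
        label = iri_local_name(.data$property)
      ),
      size = 2.6, colour = "grey30"
    ) +
    ggplot2::geom_label(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name)
    ) +
    ggplot2::theme_void()
}
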