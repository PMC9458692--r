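#' PageRank centrality of knowledge-graph resources
#'
#' Standard PageRank by power iteration on the directed resource graph: one
#' node per IRI occurring as a subject or as an IRI object, one edge per
#' triple whose object is an IRI (so `rdf:type` assertions feed centrality
#' into class nodes, which is what makes metadata matches outrank instance
#' matches downstream). Literals are not nodes. Dangling mass is
#' redistributed uniformly, the usual convention.
#'
#' @param graph A [kg()] object (non-empty).
#' @param damping Damping factor in (0,1); default 0.85.
#' @param tolerance L1 convergence tolerance on successive iterates.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return A tibble with columns `uri` and `pagerank`, sorted by `uri`;
#'   scores sum to 1. Attributes `damping` and `iterations` record the run.
#' @export
pagerank_scores <- function(graph, damping = 0.85, tolerance = 1e-12, max_iter = 1000L) {
  if (nrow(graph) == 0) stop("pagerank_scores(): empty graph", call. = FALSE)
  stopifnot(damping > 0, damping < 1)
  edges <- graph[graph$object_kind == "iri", c("subject", "object")]
  nodes <- sort(unique(c(graph$subject, edges$object)))
  n <- length(nodes)
  if (n == 1) {
    out <- tibble::tibble(uri = nodes, pagerank = 1)
    attr(out, "damping") <- damping
    attr(out, "iterations") <- 0L
    return(out)
  }
  from <- match(edges$subject, nodes)
  to <- match(edges$object, nodes)
  outdeg <- tabulate(from, nbins = n)
  r <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    contrib <- ifelse(outdeg > 0, r / outdeg, 0)
    flow <- numeric(n)
    inflow <- tapply(contrib[from], to, sum)
    flow[as.integer(names(inflow))] <- inflow
    dangling <- sum(r[outdeg == 0])
    r_new <- (1 - damping) / n + damping * (flow + dangling / n)
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < tolerance) {
      out <- tibble::tibble(uri = nodes, pagerank = r)
      attr(out, "damping") <- damping
      attr(out, "iterations") <- iter
      return(out)
    }
  }
  stop(
    "pagerank_scores(): no convergence after ", max_iter,
    " iterations (residual ", signif(delta, 3), ")",
    call. = FALSE
  )
}
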