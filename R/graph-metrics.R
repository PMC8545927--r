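# Node centralities and global topology of undirected simple graphs.
# Standard measures are delegated to igraph; the conventions (betweenness
# normalization by (n-1)(n-2)/2, strict closeness, clustering of degree<2
# nodes counted as 0) are pinned down here because they change the values.

as_simple_undirected <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  g <- igraph::as_undirected(graph, mode = "collapse")
  before <- igraph::ecount(g)
  g <- igraph::simplify(g)
  dropped <- before - igraph::ecount(g)
  if (dropped > 0) {
    inform(sprintf("Dropped %d self-loop/parallel edge(s).", dropped))
  }
  g
}

require_connected <- function(graph, caller) {
  if (!igraph::is_connected(graph)) {
    abort(sprintf(
      "%s() needs a connected graph; extract it first with giant_component().",
      caller
    ), class = "comorbnet_disconnected_error")
  }
}

#' Largest connected component of a graph
#'
#' @param graph An igraph object (made undirected and simple first).
#' @return The induced subgraph on the largest component. Size ties are
#'   broken deterministically in favor of the component containing the
#'   lexicographically smallest node id.
#' @export
giant_component <- function(graph) {
  g <- as_simple_undirected(graph)
  if (igraph::vcount(g) == 0) {
    abort("Graph has no nodes.", class = "comorbnet_validation_error")
  }
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, "")
    best <- best[order(firsts)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Node centralities: degree, betweenness, closeness
#'
#' Degree is the node's edge count. Betweenness is the proportion of
#' all-pairs shortest paths passing through the node, normalized by
#' `(n-1)(n-2)/2` so that it lies in `[0, 1]`. Closeness is
#' `(n-1) / sum of distances` to all other nodes (strict, not harmonic).
#'
#' @param graph A connected undirected igraph (use [giant_component()]
#'   first on disconnected input).
#' @return Tibble `node`, `degree`, `betweenness`, `closeness`, sorted by
#'   betweenness descending.
#' @export
graph_centralities <- function(graph) {
  g <- as_simple_undirected(graph)
  require_connected(g, "graph_centralities")
  tibble(
    node = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                             normalized = TRUE)),
    closeness = unname(igraph::closeness(g, normalized = TRUE))
  ) |>
    arrange(desc(.data$betweenness), .data$node)
}

#' Global topology of a connected graph
#'
#' @param graph A connected undirected igraph.
#' @return One-row tibble: `n_nodes`, `n_links`, `avg_degree` (`2|E|/|V|`),
#'   `diameter` (largest shortest-path length), `mspl` (mean shortest path
#'   length over unordered node pairs) and `acc` (average local clustering
#'   coefficient; nodes of degree < 2 contribute 0).
#' @export
graph_global_metrics <- function(graph) {
  g <- as_simple_undirected(graph)
  require_connected(g, "graph_global_metrics")
  tibble(
    n_nodes = igraph::vcount(g),
    n_links = igraph::ecount(g),
    avg_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
    diameter = as.integer(igraph::diameter(g, directed = FALSE,
                                           unconnected = FALSE)),
    mspl = igraph::mean_distance(g, directed = FALSE),
    acc = igraph::transitivity(g, type = "localaverage", isolates = "zero")
  )
}
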