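# High-betweenness backbone extraction and the hub / bottleneck / date-hub
# role taxonomy on protein interaction graphs.

#' Thresholds for backbone extraction and role classification
#'
#' All three fractions are rank-based with tie extension: the cutoff is the
#' centrality value of the `ceiling(fraction * n)`-th ranked node and every
#' node at or above that value is selected. Explicit value thresholds
#' (`hub_min_degree`, `bottleneck_min_bc`) override the rank-based ones
#' when supplied -- useful for reproducing published cutoffs (e.g. a hub
#' rule of DC >= 12 with a bottleneck rule of BC >= 0.0344).
#'
#' @param backbone_fraction Top fraction of nodes by betweenness kept in
#'   the backbone (default 0.20).
#' @param hub_fraction Top fraction by degree defining hubs (default 0.10).
#' @param bottleneck_fraction Top fraction by betweenness defining
#'   bottlenecks (default 0.10).
#' @param hub_min_degree,bottleneck_min_bc Optional explicit value cutoffs.
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(backbone_fraction = 0.20, hub_fraction = 0.10,
                             bottleneck_fraction = 0.10,
                             hub_min_degree = NULL,
                             bottleneck_min_bc = NULL) {
  fracs <- c(backbone_fraction, hub_fraction, bottleneck_fraction)
  if (any(fracs <= 0 | fracs > 1)) {
    abort("All fractions must lie in (0, 1].",
          class = "comorbnet_validation_error")
  }
  structure(list(backbone_fraction = backbone_fraction,
                 hub_fraction = hub_fraction,
                 bottleneck_fraction = bottleneck_fraction,
                 hub_min_degree = hub_min_degree,
                 bottleneck_min_bc = bottleneck_min_bc),
            class = "threshold_config")
}

# Rank-based cutoff value: the ceiling(fraction * n)-th largest value.
rank_cutoff <- function(values, fraction) {
  k <- ceiling(fraction * length(values))
  if (k < 1) {
    abort("Fraction selects zero nodes.", class = "comorbnet_validation_error")
  }
  sort(values, decreasing = TRUE)[k]
}

#' Extract the high-betweenness backbone of a graph
#'
#' Selects the top `backbone_fraction` of nodes by betweenness centrality
#' (rank-based, ties at the cutoff included) and returns the induced
#' subgraph, which may be disconnected.
#'
#' @param graph A connected undirected igraph.
#' @param records Optional centrality tibble from [graph_centralities()];
#'   computed from `graph` when omitted. Must cover all graph nodes.
#' @param cfg A [threshold_config()].
#' @return Object of class `backbone`: list with `graph` (induced igraph),
#'   `records` (centralities of the selected nodes), `bc_cutoff`,
#'   `n_total` and `cfg`.
#' @export
extract_backbone <- function(graph, records = NULL,
                             cfg = threshold_config()) {
  g <- as_simple_undirected(graph)
  require_connected(g, "extract_backbone")
  records <- records %||% graph_centralities(g)
  if (!setequal(records$node, igraph::V(g)$name)) {
    abort("`records` must cover exactly the nodes of `graph`.",
          class = "comorbnet_validation_error")
  }
  cutoff <- rank_cutoff(records$betweenness, cfg$backbone_fraction)
  selected <- filter(records, .data$betweenness >= cutoff)
  sub <- igraph::induced_subgraph(g, selected$node)
  structure(
    list(graph = sub, records = arrange(selected, desc(.data$betweenness)),
         bc_cutoff = cutoff, n_total = nrow(records), cfg = cfg),
    class = "backbone"
  )
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf(
    "<backbone> %d of %d nodes (top %.0f%% betweenness, BC >= %.4g), %d links\n",
    nrow(x$records), x$n_total, 100 * x$cfg$backbone_fraction, x$bc_cutoff,
    igraph::ecount(x$graph)
  ))
  invisible(x)
}

#' Classify nodes into the hub / bottleneck role taxonomy
#'
#' Hubs are nodes in the top `hub_fraction` by degree; bottlenecks the top
#' `bottleneck_fraction` by betweenness (rank-based with tie extension, or
#' explicit value cutoffs from the config). Roles follow the date-hub /
#' party-hub taxonomy: a *date-hub* is both hub and bottleneck (a connector
#' between functional modules), a *party-hub* is a hub that is not a
#' bottleneck (an intra-module hub), a *nonhub-bottleneck* is a bottleneck
#' that is not a hub; everything else is `other`.
#'
#' @param records Centrality tibble (`node`, `degree`, `betweenness`), e.g.
#'   from [graph_centralities()] on the giant component -- the ranks (and
#'   hence thresholds) are relative to whatever population `records` holds.
#' @param cfg A [threshold_config()].
#' @return Tibble `node`, `degree`, `betweenness`, `is_hub`,
#'   `is_bottleneck`, `role`.
#' @export
classify_roles <- function(records, cfg = threshold_config()) {
  records <- as_tibble(records)
  stopifnot(all(c("node", "degree", "betweenness") %in% names(records)),
            nrow(records) > 0)
  dc_min <- cfg$hub_min_degree %||%
    rank_cutoff(records$degree, cfg$hub_fraction)
  bc_min <- cfg$bottleneck_min_bc %||%
    rank_cutoff(records$betweenness, cfg$bottleneck_fraction)
  records |>
    mutate(
      is_hub = .data$degree >= dc_min,
      is_bottleneck = .data$betweenness >= bc_min,
      role = case_when(
        .data$is_hub & .data$is_bottleneck ~ "date-hub",
        .data$is_hub & !.data$is_bottleneck ~ "party-hub",
        !.data$is_hub & .data$is_bottleneck ~ "nonhub-bottleneck",
        TRUE ~ "other"
      )
    )
}

#' Summary statistics of a backbone
#'
#' @param b A `backbone` object or a centrality tibble of backbone nodes.
#' @return One-row tibble: node and link counts (links `NA` when only a
#'   record table is given) and arithmetic means of degree, betweenness and
#'   closeness over backbone nodes.
#' @export
summarize_backbone <- function(b) {
  if (inherits(b, "backbone")) {
    records <- b$records
    n_links <- igraph::ecount(b$graph)
  } else {
    records <- as_tibble(b)
    n_links <- NA_integer_
  }
  stopifnot(nrow(records) > 0)
  tibble(
    n_nodes = nrow(records), n_links = n_links,
    mean_degree = mean(records$degree),
    mean_betweenness = mean(records$betweenness),
    mean_closeness = mean(records$closeness)
  )
}

#' @rdname extract_backbone
#' @param x A `backbone` object.
#' @param ... Unused.
#' @export
tidy.backbone <- function(x, ...) x$records

#' @rdname extract_backbone
#' @export
glance.backbone <- function(x, ...) summarize_backbone(x)
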