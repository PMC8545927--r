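# ggplot2 views of the result objects. Layouts come from igraph; the plots
# are diagnostic, not publication styling.

graph_layout_tbl <- function(g, seed = 42L) {
  withr::local_seed(seed)
  xy <- igraph::layout_with_fr(g)
  tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

#' Plot a phenotypic disease network
#'
#' Force-directed layout with nodes colored by disease category and edge
#' opacity scaled by phi.
#'
#' @param object A `pdn` object.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pdn <- function(object, seed = 42L, ...) {
  if (nrow(object$links) == 0) {
    abort("Cannot plot an empty PDN.", class = "comorbnet_validation_error")
  }
  g <- igraph::graph_from_data_frame(
    object$links[, c("code_i", "code_j", "phi")], directed = FALSE,
    vertices = object$nodes$code
  )
  lay <- graph_layout_tbl(g, seed)
  seg <- object$links |>
    left_join(rename(lay, code_i = "node", x1 = "x", y1 = "y"), by = "code_i") |>
    left_join(rename(lay, code_j = "node", x2 = "x", y2 = "y"), by = "code_j")
  nodes <- left_join(lay, object$nodes, by = c(node = "code"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2,
                   yend = .data$y2, alpha = .data$phi),
      color = "grey40"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$category,
                   size = .data$n)
    ) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("PDN: %d nodes, %d links",
                                  nrow(object$nodes), nrow(object$links)),
                  size = "prevalence", alpha = "phi")
}

#' Plot backbone roles in degree-betweenness space
#'
#' @param object A `backbone` object or a role tibble from
#'   [classify_roles()].
#' @param cfg Thresholds used when `object` is a backbone (defaults to the
#'   ones stored in it).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_roles <- function(object, cfg = NULL, ...) {
  roles <- if (inherits(object, "backbone")) {
    classify_roles(object$records, cfg %||% object$cfg)
  } else {
    as_tibble(object)
  }
  ggplot2::ggplot(roles, ggplot2::aes(x = .data$degree,
                                      y = .data$betweenness,
                                      color = .data$role)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "degree (DC)", y = "betweenness (BC)",
                  title = "Hub/bottleneck role classification") +
    ggplot2::theme_minimal()
}

#' @rdname plot_roles
#' @export
autoplot.backbone <- function(object, ...) plot_roles(object, ...)

#' Degree distribution of a bipartite network
#'
#' @param object A `bipartite_network`.
#' @param ... Unused.
#' @return A ggplot object (per-side degree histograms).
#' @export
autoplot.bipartite_network <- function(object, ...) {
  deg <- bipartite_degrees(object)
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue",
                            color = "white") +
    ggplot2::facet_wrap(~side, scales = "free") +
    ggplot2::labs(x = "degree", y = "nodes",
                  title = "Bipartite degree distribution") +
    ggplot2::theme_minimal()
}

#' Plot a category-composition comparison
#'
#' Side-by-side category proportions of two disease networks, stars marking
#' categories whose two-sample proportion test is significant.
#'
#' @param comparison Tibble from [compare_profiles()].
#' @param labels Length-2 names of the two networks.
#' @return A ggplot object.
#' @export
plot_category_comparison <- function(comparison, labels = c("A", "B")) {
  long <- comparison |>
    select("category", "prop_a", "prop_b", "significant") |>
    tidyr::pivot_longer(c("prop_a", "prop_b"), names_to = "network",
                        values_to = "proportion") |>
    mutate(network = if_else(.data$network == "prop_a",
                             labels[1], labels[2]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$proportion,
                                     y = .data$category,
                                     fill = .data$network)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(
      data = filter(long, .data$significant),
      ggplot2::aes(label = "*"), position = ggplot2::position_dodge(0.9),
      hjust = -0.5
    ) +
    ggplot2::labs(x = "share of network nodes", y = NULL,
                  title = "Disease-category composition") +
    ggplot2::theme_minimal()
}
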