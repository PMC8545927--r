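# Readers and writers for the plain-text interchange formats: claims CSV,
# graph files (GraphML / 2-column TSV edge lists), PDN and backbone exports.

#' Read and write claims tables
#'
#' Claims CSV schema: header
#' `patient_id,sex,age,admission_date,dx1,dx2,dx3,dx4,dx5`, dates ISO-8601,
#' ICD-9-CM codes with or without the decimal point (stored canonically
#' without it). `dx2`..`dx5` may be empty.
#'
#' @param path CSV file path.
#' @return `read_claims()`: a claims tibble; `write_claims()`: `path`,
#'   invisibly.
#' @export
read_claims <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         patient_id = readr::col_character(),
                         sex = readr::col_character(),
                         age = readr::col_integer(),
                         admission_date = readr::col_date(),
                         .default = readr::col_character()
                       ))
  for (col in paste0("dx", 1:5)) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
    x[[col]] <- ifelse(is.na(x[[col]]) | x[[col]] == "", NA_character_,
                       icd_canonicalize(x[[col]]))
  }
  x
}

#' @rdname read_claims
#' @param claims Claims tibble.
#' @export
write_claims <- function(claims, path) {
  readr::write_csv(claims, path, na = "")
  invisible(path)
}

#' Read a graph from GraphML or a TSV edge list
#'
#' @param path `.graphml` file, or a 2-column (tab-separated) edge list;
#'   node ids are strings. The graph is made undirected and simple.
#' @return An igraph object.
#' @export
read_graph_file <- function(path) {
  g <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::read_graph(path, format = "graphml")
  } else {
    el <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                          show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
    igraph::graph_from_edgelist(as.matrix(el[, 1:2]), directed = FALSE)
  }
  as_simple_undirected(g)
}

#' Write a graph to GraphML
#'
#' @param graph An igraph object.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Export a phenotypic disease network
#'
#' Writes a GraphML file (node attributes `category` and `prevalence`,
#' edge attribute `phi`) and a TSV link table
#' `code_i  code_j  n_ij  phi`.
#'
#' @param pdn A `pdn` object.
#' @param graphml_path,links_path Output paths (either may be `NULL` to
#'   skip that file).
#' @return The `pdn`, invisibly.
#' @export
write_pdn <- function(pdn, graphml_path = NULL, links_path = NULL) {
  stopifnot(inherits(pdn, "pdn"))
  if (!is.null(links_path)) {
    readr::write_tsv(pdn$links, links_path)
  }
  if (!is.null(graphml_path)) {
    if (nrow(pdn$links) == 0) {
      warn("Empty PDN: writing a graph with no edges.")
    }
    g <- igraph::graph_from_data_frame(
      pdn$links[, c("code_i", "code_j", "phi")],
      directed = FALSE,
      vertices = tibble(name = pdn$nodes$code,
                        category = pdn$nodes$category,
                        prevalence = pdn$nodes$n)
    )
    write_graphml(g, graphml_path)
  }
  invisible(pdn)
}

#' Read a PDN link table written by [write_pdn()]
#'
#' @param path TSV link table path.
#' @return Tibble `code_i`, `code_j`, `n_ij`, `phi`.
#' @export
read_pdn_links <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    code_i = readr::col_character(),
                    code_j = readr::col_character(),
                    n_ij = readr::col_integer(),
                    phi = readr::col_double()
                  ))
}

#' Export a backbone with roles as GraphML and a TSV role table
#'
#' @param b A `backbone` object.
#' @param roles Role tibble from [classify_roles()] covering the backbone
#'   nodes (computed with default thresholds from the backbone records when
#'   omitted).
#' @param graphml_path,table_path Output paths (`NULL` skips).
#' @return The role tibble, invisibly.
#' @export
write_backbone <- function(b, roles = NULL, graphml_path = NULL,
                           table_path = NULL) {
  stopifnot(inherits(b, "backbone"))
  roles <- roles %||% classify_roles(b$records, b$cfg)
  tab <- left_join(b$records, select(roles, "node", "is_hub",
                                     "is_bottleneck", "role"),
                   by = "node")
  if (!is.null(table_path)) readr::write_tsv(tab, table_path)
  if (!is.null(graphml_path)) {
    g <- b$graph
    m <- match(igraph::V(g)$name, tab$node)
    igraph::V(g)$degree <- tab$degree[m]
    igraph::V(g)$betweenness <- tab$betweenness[m]
    igraph::V(g)$closeness <- tab$closeness[m]
    igraph::V(g)$role <- tab$role[m]
    write_graphml(g, graphml_path)
  }
  invisible(tab)
}

#' Export centrality records as TSV
#'
#' Writes `node  degree  betweenness  closeness` sorted by betweenness
#' descending.
#'
#' @param records Tibble from [graph_centralities()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_centralities <- function(records, path) {
  readr::write_tsv(arrange(records, desc(.data$betweenness)), path)
  invisible(path)
}

#' Export a bipartite network
#'
#' Writes the TSV edge list and/or a GraphML bipartite graph with a `side`
#' node attribute.
#'
#' @param net A `bipartite_network`.
#' @param edges_path,graphml_path Output paths (`NULL` skips).
#' @return The network, invisibly.
#' @export
write_bipartite <- function(net, edges_path = NULL, graphml_path = NULL) {
  stopifnot(inherits(net, "bipartite_network"))
  if (!is.null(edges_path)) readr::write_tsv(net$edges, edges_path)
  if (!is.null(graphml_path)) write_graphml(as_igraph_bipartite(net),
                                            graphml_path)
  invisible(net)
}
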