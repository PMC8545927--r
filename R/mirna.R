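# Protein-miRNA bipartite analysis: name canonicalization, intersection of
# disease-associated miRNA sets with target maps, degrees and hubs.

#' Default miRNA name alias table
#'
#' Packaged, editable corrections applied during canonicalization. Matched
#' as family prefixes on the canonical form (arm suffixes preserved); by
#' default only the evident `leg-7g` -> `let-7g` typo is corrected.
#'
#' @return Tibble with columns `from`, `to`.
#' @export
default_mirna_aliases <- function() {
  readr::read_tsv(
    system.file("extdata", "mirna_aliases.tsv", package = "comorbnet"),
    comment = "#", show_col_types = FALSE
  )
}

#' Canonicalize miRNA names
#'
#' Case-folds, strips a leading `hsa-` species prefix, and applies the
#' alias table as family-prefix substitutions. Arm suffixes (`-5p`/`-3p`)
#' are preserved and unsuffixed names stay distinct from suffixed forms
#' (merging them would silently change degree counts). The transformation
#' is idempotent.
#'
#' @param x Character vector of raw miRNA names.
#' @param aliases Alias tibble (`from`, `to`), default
#'   [default_mirna_aliases()].
#' @return Character vector of canonical names.
#' @examples
#' canonicalize_mirna(c("hsa-miR-155-5p", "leg-7g-3p"))
#' @export
canonicalize_mirna <- function(x, aliases = default_mirna_aliases()) {
  x <- trimws(as.character(x))
  if (any(is.na(x) | x == "")) {
    abort("miRNA names must be nonempty strings.",
          class = "comorbnet_validation_error")
  }
  out <- tolower(x)
  out <- sub("^hsa-", "", out)
  for (r in seq_len(nrow(aliases))) {
    from <- tolower(aliases$from[r]); to <- tolower(aliases$to[r])
    hit <- out == from | startsWith(out, paste0(from, "-"))
    out[hit] <- paste0(to, substr(out[hit], nchar(from) + 1L, nchar(out[hit])))
  }
  out
}

#' Read a disease-miRNA set (one name per line)
#'
#' @param path File with one miRNA name per line; `#` starts a comment.
#' @return Character vector of raw names.
#' @export
read_mirna_set <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines[lines != ""]
}

#' Read a protein-to-miRNA target map
#'
#' @param path TSV with columns `protein` and `mirna`.
#' @return Tibble `protein`, `mirna`.
#' @export
read_target_map <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Intersect a target map with a disease miRNA set
#'
#' Keeps the targeting edges whose miRNA belongs (after canonicalization of
#' both sides) to the disease-associated set. Proteins that lose all their
#' edges are retained as isolated nodes so that zero-degree proteins remain
#' visible in the result.
#'
#' @param target_map Tibble/data frame `protein`, `mirna` (e.g. a target
#'   database export restricted to backbone proteins).
#' @param disease_set Character vector of disease-associated miRNA names.
#' @param aliases Alias table for canonicalization.
#' @return A [bipartite_network()].
#' @export
intersect_mirna_sets <- function(target_map, disease_set,
                                 aliases = default_mirna_aliases()) {
  target_map <- as_tibble(target_map)
  stopifnot(nrow(target_map) > 0, length(disease_set) > 0)
  disease <- unique(canonicalize_mirna(disease_set, aliases))
  target_map$mirna <- canonicalize_mirna(target_map$mirna, aliases)
  kept <- filter(target_map, .data$mirna %in% disease)
  bipartite_network(kept, proteins = unique(target_map$protein),
                    canonicalize = FALSE)
}

#' Node degrees of a bipartite network
#'
#' @param net A `bipartite_network`.
#' @return Tibble `node`, `side` (`"protein"`/`"mirna"`), `degree`;
#'   isolated nodes have degree 0. The handshake identity holds: protein
#'   degrees and miRNA degrees both sum to the edge count.
#' @export
bipartite_degrees <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  prot <- tibble(node = net$proteins, side = "protein") |>
    left_join(count(net$edges, node = .data$protein), by = "node")
  mir <- tibble(node = net$mirnas, side = "mirna") |>
    left_join(count(net$edges, node = .data$mirna), by = "node")
  bind_rows(prot, mir) |>
    mutate(degree = tidyr::replace_na(.data$n, 0L)) |>
    select("node", "side", "degree")
}

#' Hub thresholds for a bipartite network
#'
#' @param protein_hub_min_mirnas Minimum number of targeting miRNAs for a
#'   protein to count as a hub (default 11, i.e. "more than 10").
#' @param mirna_hub_min_proteins Minimum number of targeted proteins for a
#'   miRNA hub (default 13, i.e. "more than 12").
#' @return Object of class `hub_thresholds`.
#' @export
hub_thresholds <- function(protein_hub_min_mirnas = 11,
                           mirna_hub_min_proteins = 13) {
  stopifnot(protein_hub_min_mirnas >= 1, mirna_hub_min_proteins >= 1)
  structure(list(protein_hub_min_mirnas = as.integer(protein_hub_min_mirnas),
                 mirna_hub_min_proteins = as.integer(mirna_hub_min_proteins)),
            class = "hub_thresholds")
}

#' Hub proteins and hub miRNAs of a bipartite network
#'
#' @param net A `bipartite_network`.
#' @param thresholds A [hub_thresholds()].
#' @return List with sorted character vectors `proteins` and `mirnas`.
#' @export
find_hubs <- function(net, thresholds = hub_thresholds()) {
  deg <- bipartite_degrees(net)
  list(
    proteins = sort(deg$node[deg$side == "protein" &
                               deg$degree >= thresholds$protein_hub_min_mirnas]),
    mirnas = sort(deg$node[deg$side == "mirna" &
                             deg$degree >= thresholds$mirna_hub_min_proteins])
  )
}

#' Convert a bipartite network to igraph
#'
#' @param net A `bipartite_network`.
#' @return Undirected igraph with a `side` vertex attribute
#'   (`"protein"`/`"mirna"`) and `type` logical (TRUE for miRNAs).
#' @export
as_igraph_bipartite <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = tibble(
      name = c(net$proteins, net$mirnas),
      side = c(rep("protein", length(net$proteins)),
               rep("mirna", length(net$mirnas)))
    )
  )
  igraph::V(g)$type <- igraph::V(g)$side == "mirna"
  g
}
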