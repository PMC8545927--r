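# Packaged fixtures transcribed from the published summary tables:
# table1 -- diabetic inpatient counts by age group and type;
# table2 -- the 46 top-betweenness proteins of the interactome giant
#           component with their centralities and seed flags;
# table3 -- KEGG pathway membership lists of the backbone proteins;
# table4 -- the protein-miRNA targeting edge list (plus printed per-protein
#           counts used as a self-consistency check).

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "comorbnet")
  if (path == "") {
    abort(sprintf("Packaged fixture '%s' not found.", file),
          class = "comorbnet_integrity_error")
  }
  path
}

#' Load a packaged fixture
#'
#' @param name One of `"table1"` (DM inpatient counts by age group),
#'   `"table2"` (46 backbone protein centralities with seed flags),
#'   `"table3"` (KEGG pathway membership lists), `"table4"` (protein-miRNA
#'   bipartite network).
#' @return `table1`/`table2`: a tibble; `table3`: a pathway tibble as from
#'   [read_gmt()]; `table4`: a [bipartite_network()] with the printed
#'   per-protein counts attached as attribute `"printed_counts"`.
#' @examples
#' nrow(load_fixture("table2"))
#' @export
load_fixture <- function(name) {
  switch(
    name,
    table1 = {
      x <- readr::read_tsv(fixture_path("table1_dm_counts.tsv"),
                           show_col_types = FALSE)
      bad <- with(x, t1d + t2d + others != total)
      if (nrow(x) != 10 || any(bad)) {
        abort("table1 fixture failed its integrity check (row sums).",
              class = "comorbnet_integrity_error")
      }
      x
    },
    table2 = {
      x <- readr::read_tsv(fixture_path("table2_centralities.tsv"),
                           show_col_types = FALSE)
      needed <- c("protein", "degree", "betweenness", "closeness", "is_seed")
      if (!all(needed %in% names(x)) || nrow(x) != 46 || sum(x$is_seed) != 11) {
        abort("table2 fixture failed its integrity check (46 rows, 11 seeds).",
              class = "comorbnet_integrity_error")
      }
      select(x, dplyr::all_of(c("rank", needed)))
    },
    table3 = read_gmt(fixture_path("table3_pathways.gmt")),
    table4 = {
      edges <- readr::read_tsv(fixture_path("table4_edges.tsv"),
                               show_col_types = FALSE)
      counts <- readr::read_tsv(fixture_path("table4_counts.tsv"),
                                show_col_types = FALSE)
      net <- bipartite_network(edges, proteins = counts$protein)
      deg <- bipartite_degrees(net)
      got <- setNames(deg$degree[deg$side == "protein"],
                      deg$node[deg$side == "protein"])
      if (!all(got[counts$protein] == counts$n_mirnas)) {
        abort("table4 fixture failed its integrity check (printed per-protein counts).",
              class = "comorbnet_integrity_error")
      }
      attr(net, "printed_counts") <- counts
      net
    },
    abort(sprintf("Unknown fixture '%s'; use table1..table4.", name),
          class = "comorbnet_validation_error")
  )
}
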