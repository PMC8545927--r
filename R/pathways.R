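# Pathway membership overlap: set intersection of a node list against
# packaged (or user-supplied GMT) pathway member lists. Membership counts
# only -- no enrichment statistic is computed.

#' Read gene sets in GMT format
#'
#' One pathway per line: `pathway_id<TAB>description<TAB>member...`.
#'
#' @param path Path to a GMT file.
#' @return Tibble `pathway_id`, `description`, `members` (list column of
#'   character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[trimws(lines) != ""]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(which(bad), collapse = ", ")),
          class = "comorbnet_parse_error")
  }
  tibble(
    pathway_id = vapply(parts, `[[`, "", 1),
    description = vapply(parts, `[[`, "", 2),
    members = lapply(parts, function(p) unique(trimws(p[-(1:2)])))
  )
}

#' Overlap of a node set with pathway membership lists
#'
#' For each pathway, the intersection of its members with `nodes`
#' (case-insensitively, both sides upper-cased), its size, and the sorted
#' member list.
#'
#' @param nodes Character vector of protein/gene ids (e.g. backbone nodes).
#' @param pathways Tibble as returned by [read_gmt()] or
#'   [load_fixture()]`("table3")`.
#' @return Tibble `pathway_id`, `description`, `n_overlap`, `overlap`
#'   (list column of sorted intersections), in the input pathway order.
#' @export
annotate_pathways <- function(nodes, pathways) {
  stopifnot(length(nodes) > 0, nrow(pathways) > 0)
  if (anyDuplicated(pathways$pathway_id)) {
    abort("Duplicate pathway ids in the pathway collection.",
          class = "comorbnet_validation_error")
  }
  nodes_uc <- unique(toupper(nodes))
  pathways |>
    mutate(
      overlap = purrr::map(.data$members,
                           ~ sort(intersect(toupper(.x), nodes_uc))),
      n_overlap = lengths(.data$overlap)
    ) |>
    select("pathway_id", "description", "n_overlap", "overlap")
}
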