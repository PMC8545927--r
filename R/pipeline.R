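# End-to-end composition: simulate -> PDN -> category comparison, and
# fixtures -> backbone roles -> bipartite hubs -> pathway overlap, with all
# outputs plus a machine-readable run manifest written to one directory.

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()]. All randomness is funneled
#' through the single `seed`.
#'
#' @param n_patients Synthetic cohort size (default 4000 -- the demo chain
#'   completes in seconds at this size).
#' @param node_level ICD digit level for PDN nodes (3, 4 or 5).
#' @param threshold_fraction Top fraction of comorbidity links retained.
#' @param thresholds A [threshold_config()]; the default pins the published
#'   value cutoffs (hub DC >= 12, bottleneck BC >= 0.0344) used on the
#'   packaged centrality fixture.
#' @param hubs A [hub_thresholds()].
#' @param alpha Significance level of the category comparison.
#' @param seed Integer seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 4000, node_level = 3,
                            threshold_fraction = 0.006,
                            thresholds = threshold_config(
                              hub_min_degree = 12,
                              bottleneck_min_bc = 0.0344
                            ),
                            hubs = hub_thresholds(), alpha = 0.05,
                            seed = 1L) {
  stopifnot(node_level %in% c(3, 4, 5),
            threshold_fraction > 0, threshold_fraction <= 1,
            inherits(thresholds, "threshold_config"),
            inherits(hubs, "hub_thresholds"))
  structure(list(n_patients = as.integer(n_patients),
                 node_level = as.integer(node_level),
                 threshold_fraction = threshold_fraction,
                 thresholds = thresholds, hubs = hubs, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the [pipeline_config()] defaults; nested
#' `thresholds:` and `hubs:` mappings override those of
#' [threshold_config()] and [hub_thresholds()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("n_patients", "node_level",
                                  "threshold_fraction", "alpha", "seed"))]
  if (!is.null(y$thresholds)) {
    args$thresholds <- do.call(threshold_config, y$thresholds)
  }
  if (!is.null(y$hubs)) args$hubs <- do.call(hub_thresholds, y$hubs)
  do.call(pipeline_config, args)
}

#' Run the full analysis chain
#'
#' Executes two branches and writes every output plus a `manifest.json`
#' (configuration, seed, package version, output checksums) to `out_dir`:
#'
#' 1. *Claims branch*: simulate a T1D inpatient cohort, build one
#'    phenotypic disease network per sex, profile the 13 disease
#'    categories and compare the male and female profiles with
#'    two-sample proportion tests.
#' 2. *Fixture branch*: classify the packaged backbone centrality records
#'    into date-hub / party-hub / nonhub-bottleneck roles, summarize the
#'    backbone, compute protein and miRNA degrees and hubs of the packaged
#'    bipartite network, and annotate the backbone proteins against the
#'    packaged pathway lists.
#'
#' @param config A [pipeline_config()], or a path to a YAML file for
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with all intermediate results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  stages <- character()
  stage <- function(name) {
    inform(sprintf("[comorbnet] stage: %s", name))
    stages <<- c(stages, name)
  }

  stage("simulate")
  spec <- default_cohort_spec(n_patients = config$n_patients,
                              seed = config$seed)
  claims <- simulate_claims(spec)
  write_claims(claims, path("claims.csv"))

  stage("pdn")
  pdns <- lapply(c(M = "M", F = "F"), function(sx) {
    counts <- count_prevalences(claims, dm_type = "T1D", sex = sx,
                                node_level = config$node_level)
    build_pdn(counts, config$threshold_fraction,
              stratum = paste0("T1D/", sx))
  })
  write_pdn(pdns$M, path("pdn_male.graphml"), path("pdn_male_links.tsv"))
  write_pdn(pdns$F, path("pdn_female.graphml"), path("pdn_female_links.tsv"))

  stage("compare")
  comparison <- compare_profiles(category_profile(pdns$M),
                                 category_profile(pdns$F),
                                 alpha = config$alpha)
  readr::write_tsv(comparison, path("category_comparison.tsv"))

  stage("backbone")
  table2 <- load_fixture("table2")
  records <- rename(table2, node = "protein")
  roles <- classify_roles(records, config$thresholds)
  backbone_summary <- summarize_backbone(records)
  readr::write_tsv(roles, path("backbone_roles.tsv"))
  readr::write_tsv(backbone_summary, path("backbone_summary.tsv"))

  stage("mirna")
  net <- load_fixture("table4")
  degrees <- bipartite_degrees(net)
  hubs <- find_hubs(net, config$hubs)
  write_bipartite(net, path("bipartite_edges.tsv"),
                  path("bipartite.graphml"))
  readr::write_tsv(degrees, path("bipartite_degrees.tsv"))
  jsonlite::write_json(hubs, path("hubs.json"), auto_unbox = FALSE,
                       pretty = TRUE)

  stage("annotate")
  pathways <- load_fixture("table3")
  overlap <- annotate_pathways(table2$protein, pathways) |>
    mutate(overlap = purrr::map_chr(.data$overlap, paste, collapse = ","))
  readr::write_tsv(overlap, path("pathway_overlap.tsv"))

  stage("manifest")
  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "comorbnet",
    version = as.character(utils::packageVersion("comorbnet")),
    seed = config$seed,
    config = list(
      n_patients = config$n_patients, node_level = config$node_level,
      threshold_fraction = config$threshold_fraction,
      thresholds = unclass(config$thresholds),
      hubs = unclass(config$hubs), alpha = config$alpha
    ),
    stages = stages,
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs
    ))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")

  invisible(list(claims = claims, pdns = pdns, comparison = comparison,
                 roles = roles, backbone_summary = backbone_summary,
                 bipartite = net, degrees = degrees, hubs = hubs,
                 pathway_overlap = overlap, manifest = manifest,
                 out_dir = out_dir))
}
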