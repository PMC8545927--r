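# Synthetic cohorts, modular graphs with planted connectors, and random
# bipartite networks. These generators provide known ground truth for every
# downstream stage, replacing restricted claims data and database exports.

#' Specify a synthetic inpatient cohort
#'
#' Defines the population from which [simulate_claims()] draws: disease
#' prevalences, pairwise comorbidity structure (planted phi-correlations),
#' demographics and diabetes-type mix. Diseases outside planted pairs are
#' sampled independently; each planted pair is sampled jointly from the
#' 2x2 table implied by its marginal prevalences and target phi, which must
#' respect the Frechet bounds
#' `max(0, p_i + p_j - 1) <= p_ij <= min(p_i, p_j)`.
#'
#' @param n_patients Number of patients.
#' @param diseases Tibble/data frame with `code` (ICD-9-CM) and `prevalence`
#'   in (0, 1); optionally used by planted pairs.
#' @param planted_pairs Optional tibble with `code_i`, `code_j`,
#'   `target_phi` in `[-1, 1]`. Codes must appear in `diseases` and a
#'   disease may belong to at most one pair.
#' @param sex_ratio Fraction of male patients (default 0.5).
#' @param age_bands Tibble with `age_min`, `age_max`, `weight` (weights sum
#'   to 1 within 1e-9).
#' @param dm_type_mix Named numeric over `T1D`, `T2D`, `other`, summing
#'   to 1: every synthetic patient is a diabetic inpatient and receives one
#'   250.xx code whose 5th digit encodes the drawn type (1/3 for T1D, 0/2
#'   for T2D, absent for other).
#' @param seed Integer seed; the single source of randomness of the draw.
#' @return A validated object of class `cohort_spec`.
#' @seealso [default_cohort_spec()] for the packaged demonstration cohort.
#' @export
cohort_spec <- function(n_patients, diseases, planted_pairs = NULL,
                        sex_ratio = 0.5,
                        age_bands = default_age_bands(),
                        dm_type_mix = c(T1D = 1, T2D = 0, other = 0),
                        seed = 1L) {
  diseases <- as_tibble(diseases)
  stopifnot(n_patients >= 1, all(c("code", "prevalence") %in% names(diseases)))
  diseases$code <- icd_canonicalize(diseases$code)
  if (anyDuplicated(diseases$code)) {
    abort("Duplicate disease codes in `diseases`.",
          class = "comorbnet_validation_error")
  }
  if (any(diseases$prevalence <= 0 | diseases$prevalence >= 1)) {
    abort("Disease prevalences must lie strictly between 0 and 1.",
          class = "comorbnet_validation_error")
  }
  if (!(sex_ratio >= 0 && sex_ratio <= 1)) {
    abort("sex_ratio must be in [0, 1].", class = "comorbnet_validation_error")
  }
  age_bands <- as_tibble(age_bands)
  if (abs(sum(age_bands$weight) - 1) > 1e-9) {
    abort("Age band weights must sum to 1 (within 1e-9).",
          class = "comorbnet_validation_error")
  }
  if (is.null(names(dm_type_mix)) ||
      !setequal(names(dm_type_mix), c("T1D", "T2D", "other")) ||
      abs(sum(dm_type_mix) - 1) > 1e-9) {
    abort("dm_type_mix must be named over {T1D, T2D, other} and sum to 1.",
          class = "comorbnet_validation_error")
  }
  if (!is.null(planted_pairs) && nrow(as_tibble(planted_pairs)) > 0) {
    planted_pairs <- as_tibble(planted_pairs) |>
      mutate(code_i = icd_canonicalize(.data$code_i),
             code_j = icd_canonicalize(.data$code_j))
    missing <- setdiff(c(planted_pairs$code_i, planted_pairs$code_j),
                       diseases$code)
    if (length(missing) > 0) {
      abort(sprintf("Planted pair codes not declared in `diseases`: %s",
                    paste(missing, collapse = ", ")),
            class = "comorbnet_validation_error")
    }
    involved <- c(planted_pairs$code_i, planted_pairs$code_j)
    if (anyDuplicated(involved)) {
      abort("Each disease may belong to at most one planted pair.",
            class = "comorbnet_validation_error")
    }
    prev <- setNames(diseases$prevalence, diseases$code)
    for (r in seq_len(nrow(planted_pairs))) {
      p_i <- prev[[planted_pairs$code_i[r]]]
      p_j <- prev[[planted_pairs$code_j[r]]]
      phi <- planted_pairs$target_phi[r]
      if (abs(phi) > 1) {
        abort("target_phi must lie in [-1, 1].",
              class = "comorbnet_validation_error")
      }
      p_ij <- p_i * p_j + phi * sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
      lo <- max(0, p_i + p_j - 1); hi <- min(p_i, p_j)
      if (p_ij < lo - 1e-12 || p_ij > hi + 1e-12) {
        abort(sprintf(
          "Infeasible planted pair (%s, %s): implied joint probability %.4f outside Frechet bounds [%.4f, %.4f].",
          planted_pairs$code_i[r], planted_pairs$code_j[r], p_ij, lo, hi
        ), class = "comorbnet_infeasible_pair_error")
      }
    }
  } else {
    planted_pairs <- tibble(code_i = character(), code_j = character(),
                            target_phi = numeric())
  }
  structure(
    list(n_patients = as.integer(n_patients), diseases = diseases,
         planted_pairs = planted_pairs, sex_ratio = sex_ratio,
         age_bands = age_bands, dm_type_mix = dm_type_mix[c("T1D", "T2D", "other")],
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default age bands of the synthetic cohort
#'
#' Ten decade bands mirroring the age-group layout of diabetic inpatient
#' summary tables, with weights proportional to the packaged inpatient
#' counts per band.
#'
#' @return Tibble with `age_min`, `age_max`, `weight`.
#' @export
default_age_bands <- function() {
  t1 <- load_fixture("table1")
  tibble(
    age_min = c(1L, seq(10L, 90L, by = 10L)),
    age_max = c(seq(9L, 89L, by = 10L), 99L),
    weight = t1$total / sum(t1$total)
  )
}

#' Demonstration cohort specification
#'
#' A small but realistic synthetic T1D inpatient cohort: ~20 background
#' diseases drawn from chapters common among diabetic comorbidities
#' (anemia, hypertension, retinal, renal, atherosclerotic disease, ...)
#' with prevalences between 2% and 12%, and two planted comorbid pairs
#' with phi = 0.30 and 0.20. Prevalence magnitudes are a documented free
#' choice: the source summary tables report no pairwise magnitudes.
#'
#' @param n_patients Cohort size (default 20000).
#' @param seed Seed (default 1).
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(n_patients = 20000, seed = 1L) {
  diseases <- tibble(
    code = c("285", "401", "379", "585", "440", "403", "276", "272",
             "414", "428", "486", "590", "682", "707", "730", "362",
             "536", "357", "581", "593"),
    prevalence = c(0.10, 0.12, 0.04, 0.06, 0.05, 0.04, 0.09, 0.08,
                   0.06, 0.05, 0.04, 0.03, 0.04, 0.03, 0.02, 0.07,
                   0.03, 0.05, 0.02, 0.03)
  )
  pairs <- tibble(
    code_i = c("285", "403"),
    code_j = c("585", "440"),
    target_phi = c(0.30, 0.20)
  )
  cohort_spec(n_patients, diseases, pairs, sex_ratio = 0.5,
              dm_type_mix = c(T1D = 1, T2D = 0, other = 0), seed = seed)
}

# Draw one planted pair jointly from its 2x2 table; returns n x 2 logical.
draw_pair <- function(n, p_i, p_j, phi) {
  p11 <- p_i * p_j + phi * sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
  p11 <- min(max(p11, max(0, p_i + p_j - 1)), min(p_i, p_j))
  p10 <- p_i - p11; p01 <- p_j - p11
  u <- runif(n)
  cbind(i = u < p11 + p10, j = u < p11 | (u >= p11 + p10 & u < p11 + p10 + p01))
}

#' Simulate an inpatient claims table
#'
#' Draws a cohort according to a [cohort_spec()]: patient demographics,
#' per-patient disease sets (independent Bernoulli draws, except planted
#' pairs drawn jointly from their 2x2 tables), one diabetes-typing 250.xx
#' code per patient, and a split of each patient's codes across 1-3
#' hospitalization claims of at most 5 diagnosis codes each. The split is
#' cosmetic: downstream counting deduplicates per patient.
#'
#' @param spec A `cohort_spec`.
#' @return Tibble with one row per claim: `patient_id`, `sex`, `age`,
#'   `admission_date`, `dx1`..`dx5`. Ground truth (per-patient disease
#'   draws, diabetes types and the spec) is attached as attribute
#'   `"truth"`.
#' @examples
#' claims <- simulate_claims(default_cohort_spec(n_patients = 500))
#' head(claims)
#' @export
simulate_claims <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n_patients
  patient_id <- sprintf("P%07d", seq_len(n))
  sex <- if_else(runif(n) < spec$sex_ratio, "M", "F")
  band <- sample.int(nrow(spec$age_bands), n, replace = TRUE,
                     prob = spec$age_bands$weight)
  age <- spec$age_bands$age_min[band] +
    floor(runif(n) * (spec$age_bands$age_max[band] -
                        spec$age_bands$age_min[band] + 1L))

  # disease indicator matrix, planted pairs first (joint), rest independent
  codes <- spec$diseases$code
  prev <- setNames(spec$diseases$prevalence, codes)
  has <- matrix(FALSE, n, length(codes), dimnames = list(NULL, codes))
  pp <- spec$planted_pairs
  for (r in seq_len(nrow(pp))) {
    d <- draw_pair(n, prev[[pp$code_i[r]]], prev[[pp$code_j[r]]],
                   pp$target_phi[r])
    has[, pp$code_i[r]] <- d[, 1]
    has[, pp$code_j[r]] <- d[, 2]
  }
  indep <- setdiff(codes, c(pp$code_i, pp$code_j))
  for (code in indep) has[, code] <- runif(n) < prev[[code]]

  dm_type <- sample(c("T1D", "T2D", "other"), n, replace = TRUE,
                    prob = spec$dm_type_mix)
  fourth <- sample(0:9, n, replace = TRUE)
  fifth <- character(n)
  fifth[dm_type == "T1D"] <- sample(c("1", "3"), sum(dm_type == "T1D"),
                                    replace = TRUE)
  fifth[dm_type == "T2D"] <- sample(c("0", "2"), sum(dm_type == "T2D"),
                                    replace = TRUE)
  dm_code <- paste0("250", fourth, fifth)

  idx <- which(has, arr.ind = TRUE)
  long <- tibble(
    row = c(seq_len(n), idx[, 1]),
    code = c(dm_code, codes[idx[, 2]])
  ) |>
    arrange(.data$row) |>
    group_by(.data$row) |>
    mutate(shuffle = sample.int(n()), n_codes = n()) |>
    ungroup()

  n_claims_raw <- sample.int(3L, n, replace = TRUE)
  long <- long |>
    mutate(
      k = pmax(n_claims_raw[.data$row], ceiling(.data$n_codes / 5)),
      claim = (.data$shuffle - 1L) %% .data$k + 1L,
      slot = (.data$shuffle - 1L) %/% .data$k + 1L
    )
  claims <- long |>
    mutate(dx = paste0("dx", .data$slot)) |>
    select("row", "claim", "dx", "code") |>
    tidyr::pivot_wider(names_from = "dx", values_from = "code") |>
    arrange(.data$row, .data$claim)
  for (col in setdiff(paste0("dx", 1:5), names(claims))) {
    claims[[col]] <- NA_character_
  }
  claims <- claims |>
    mutate(
      patient_id = patient_id[.data$row], sex = sex[.data$row],
      age = age[.data$row],
      admission_date = as.Date("2002-01-01") +
        floor(runif(n()) *
                as.integer(as.Date("2008-12-31") - as.Date("2002-01-01") + 1L))
    ) |>
    select("patient_id", "sex", "age", "admission_date",
           dplyr::all_of(paste0("dx", 1:5)))

  truth <- list(
    assignments = tibble(patient_id = patient_id[idx[, 1]],
                         code = codes[idx[, 2]]),
    dm = tibble(patient_id = patient_id, dm_type = dm_type,
                dm_code = dm_code),
    spec = spec
  )
  attr(claims, "truth") <- truth
  claims
}

#' Specify a modular graph with planted connectors
#'
#' @param n_modules Number of modules (>= 2).
#' @param module_size Nodes per module (>= 3).
#' @param n_connectors Number of planted connector nodes (>= 1), each
#'   bridging at least two modules.
#' @param intra_module_edge_prob Probability of each possible within-module
#'   edge, in (0, 1]; a random spanning path keeps each module connected
#'   regardless.
#' @param seed Integer seed.
#' @return A validated object of class `planted_graph_spec`.
#' @export
planted_graph_spec <- function(n_modules, module_size, n_connectors,
                               intra_module_edge_prob = 0.3, seed = 1L) {
  if (!(n_modules >= 2 && module_size >= 3 && n_connectors >= 1)) {
    abort("Need n_modules >= 2, module_size >= 3, n_connectors >= 1.",
          class = "comorbnet_validation_error")
  }
  if (!(intra_module_edge_prob > 0 && intra_module_edge_prob <= 1)) {
    abort("intra_module_edge_prob must be in (0, 1].",
          class = "comorbnet_validation_error")
  }
  structure(list(n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 n_connectors = as.integer(n_connectors),
                 intra_module_edge_prob = intra_module_edge_prob,
                 seed = as.integer(seed)),
            class = "planted_graph_spec")
}

#' Generate a modular graph with planted high-betweenness connectors
#'
#' Each module is an Erdos-Renyi-like subgraph (random spanning path plus
#' independent extra edges) and connector nodes bridge two or more modules
#' by a single edge into each. Connectors jointly cover a chain over all
#' modules, so the graph is connected and every inter-module shortest path
#' crosses a connector -- the ground truth for backbone extraction.
#'
#' @param spec A `planted_graph_spec` (or arguments passed to it via `...`).
#' @param ... If `spec` is missing, forwarded to [planted_graph_spec()].
#' @return List with `graph` (an undirected igraph) and `connectors`
#'   (character vector of planted connector node ids).
#' @export
simulate_planted_graph <- function(spec, ...) {
  if (!inherits(spec, "planted_graph_spec")) {
    spec <- planted_graph_spec(spec, ...)
  }
  withr::local_seed(spec$seed)
  m <- spec$n_modules; s <- spec$module_size; p <- spec$intra_module_edge_prob
  module_nodes <- lapply(seq_len(m), function(k) sprintf("M%d_%02d", k, seq_len(s)))
  edges <- list()
  for (k in seq_len(m)) {
    nodes <- sample(module_nodes[[k]])
    edges[[length(edges) + 1L]] <-
      cbind(nodes[-length(nodes)], nodes[-1])           # spanning path
    pairs <- t(utils::combn(module_nodes[[k]], 2))
    keep <- runif(nrow(pairs)) < p
    if (any(keep)) edges[[length(edges) + 1L]] <- pairs[keep, , drop = FALSE]
  }
  # connectors cover a chain of modules: contiguous overlapping segments
  n_chain <- min(spec$n_connectors, m - 1L)
  cuts <- unique(round(seq(1, m, length.out = n_chain + 1L)))
  connectors <- sprintf("C%02d", seq_len(spec$n_connectors))
  for (k in seq_len(spec$n_connectors)) {
    mods <- if (k <= n_chain) {
      seq(cuts[k], cuts[k + 1L])
    } else {
      sample.int(m, 2L)                                  # surplus connectors
    }
    anchors <- vapply(mods, function(mm) sample(module_nodes[[mm]], 1L), "")
    edges[[length(edges) + 1L]] <- cbind(connectors[k], anchors)
  }
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g)
  list(graph = g, connectors = connectors)
}

#' Constructor for a protein-miRNA bipartite network
#'
#' @param edges Tibble/data frame with columns `protein` and `mirna`.
#'   Duplicate edges are collapsed.
#' @param proteins,mirnas Optional node sets; defaults to the nodes present
#'   in `edges`, but extra isolated nodes can be declared here.
#' @param canonicalize Should miRNA names be run through
#'   [canonicalize_mirna()] (default `TRUE`)?
#' @return An object of class `bipartite_network` with `proteins`,
#'   `mirnas` and an `edges` tibble.
#' @export
bipartite_network <- function(edges, proteins = NULL, mirnas = NULL,
                              canonicalize = TRUE) {
  edges <- as_tibble(edges)
  stopifnot(all(c("protein", "mirna") %in% names(edges)))
  edges <- edges |>
    filter(!is.na(.data$protein), !is.na(.data$mirna),
           .data$protein != "", .data$mirna != "")
  if (canonicalize && nrow(edges) > 0) {
    edges$mirna <- canonicalize_mirna(edges$mirna)
  }
  if (canonicalize && !is.null(mirnas)) mirnas <- canonicalize_mirna(mirnas)
  edges <- distinct(edges, .data$protein, .data$mirna)
  structure(
    list(
      proteins = sort(union(proteins, edges$protein)),
      mirnas = sort(union(mirnas, edges$mirna)),
      edges = arrange(edges, .data$protein, .data$mirna)
    ),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %d proteins, %d miRNAs, %d edges\n",
              length(x$proteins), length(x$mirnas), nrow(x$edges)))
  invisible(x)
}

#' @rdname bipartite_network
#' @param x A `bipartite_network`.
#' @param ... Unused.
#' @export
tidy.bipartite_network <- function(x, ...) x$edges

#' @rdname bipartite_network
#' @export
glance.bipartite_network <- function(x, ...) {
  tibble(n_proteins = length(x$proteins), n_mirnas = length(x$mirnas),
         n_edges = nrow(x$edges))
}

#' Generate a random bipartite protein-miRNA network
#'
#' Independent Bernoulli edges between every (protein, miRNA) pair.
#'
#' @param n_proteins,n_mirnas Side sizes (positive integers).
#' @param edge_prob Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `bipartite_network` containing all nodes of both sides
#'   (isolated ones included).
#' @export
simulate_bipartite <- function(n_proteins, n_mirnas, edge_prob, seed = 1L) {
  stopifnot(n_proteins >= 1, n_mirnas >= 1,
            edge_prob >= 0, edge_prob <= 1)
  withr::local_seed(as.integer(seed))
  proteins <- sprintf("PROT%03d", seq_len(n_proteins))
  mirnas <- sprintf("mir-%d", seq_len(n_mirnas))
  grid <- tidyr::expand_grid(protein = proteins, mirna = mirnas)
  edges <- grid[runif(nrow(grid)) < edge_prob, ]
  bipartite_network(edges, proteins = proteins, mirnas = mirnas,
                    canonicalize = FALSE)
}
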