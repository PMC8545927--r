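#' Phi-correlation between two diseases
#'
#' The phi-correlation is the Pearson correlation of two binary
#' disease-indicator vectors, computed from the 2x2 contingency counts:
#' \deqn{\phi_{ij} = \frac{N N_{ij} - N_i N_j}
#'   {\sqrt{N_i N_j (N - N_i)(N - N_j)}}}
#' where `N` is the number of patients in the population, `N_i` and `N_j`
#' the prevalences (patient counts) of the two diseases and `N_ij` the
#' number of patients carrying both diagnoses.
#'
#' @param N Total number of patients (scalar or vector).
#' @param N_i,N_j Prevalence counts of the two diseases.
#' @param N_ij Co-occurrence count.
#' @return Numeric vector of phi values in `[-1, 1]`.
#' @examples
#' phi_correlation(1000, 100, 50, 20)
#' @export
phi_correlation <- function(N, N_i, N_j, N_ij) {
  args <- tibble(N = as.numeric(N), N_i = as.numeric(N_i),
                 N_j = as.numeric(N_j), N_ij = as.numeric(N_ij))
  N <- args$N; N_i <- args$N_i; N_j <- args$N_j; N_ij <- args$N_ij
  if (any(N_ij > pmin(N_i, N_j) | N_ij < 0, na.rm = TRUE)) {
    abort("N_ij must satisfy 0 <= N_ij <= min(N_i, N_j).",
          class = "comorbnet_validation_error")
  }
  degen <- N_i <= 0 | N_i >= N | N_j <= 0 | N_j >= N
  if (any(degen, na.rm = TRUE)) {
    abort(
      "phi is undefined when a disease is absent from, or universal in, the population (N_i or N_j in {0, N}).",
      class = "comorbnet_degenerate_error"
    )
  }
  (N * N_ij - N_i * N_j) / sqrt(N_i * N_j * (N - N_i) * (N - N_j))
}

#' Per-patient diabetes typing from ICD-9-CM codes
#'
#' The 5th digit of a 250.xx code encodes the diabetes type: 1 or 3 mean
#' type 1, 0 or 2 mean type 2. A patient is typed from the union of their
#' diagnosis codes with precedence T1D > T2D > other; `other` covers 250
#' codes with a different or absent 5th digit, `none` means no 250 code
#' at all.
#'
#' @param codes Character vector of ICD-9-CM codes (one patient's codes).
#' @return One of `"T1D"`, `"T2D"`, `"other"`, `"none"`.
#' @examples
#' classify_dm_type(c("25011", "4019"))
#' classify_dm_type("25000")
#' @export
classify_dm_type <- function(codes) {
  codes <- icd_canonicalize(codes)
  dm <- codes[substr(codes, 1, 3) == "250"]
  if (length(dm) == 0) return("none")
  fifth <- substr(dm, 5, 5)
  if (any(fifth %in% c("1", "3"))) return("T1D")
  if (any(fifth %in% c("0", "2"))) return("T2D")
  "other"
}

#' Diabetes type of every patient in a claims table
#'
#' @param claims Claims tibble as returned by [simulate_claims()] or
#'   [read_claims()] (columns `patient_id`, `dx1`..`dx5`).
#' @return Tibble with `patient_id` and `dm_type`.
#' @export
patient_dm_type <- function(claims) {
  claims_long(claims) |>
    group_by(.data$patient_id) |>
    summarise(dm_type = classify_dm_type(.data$code), .groups = "drop")
}

# Wide claims (dx1..dx5) -> long (patient_id, sex, age, code), codes canonical.
claims_long <- function(claims) {
  dx_cols <- grep("^dx[1-5]$", names(claims), value = TRUE)
  if (length(dx_cols) == 0) {
    abort("Claims table must contain dx1..dx5 diagnosis columns.",
          class = "comorbnet_validation_error")
  }
  keep <- intersect(c("patient_id", "sex", "age"), names(claims))
  claims |>
    select(dplyr::all_of(c(keep, dx_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(dx_cols), names_to = NULL,
                        values_to = "code") |>
    filter(!is.na(.data$code), .data$code != "") |>
    mutate(code = icd_canonicalize(.data$code))
}

#' Patient-level prevalence and co-occurrence counts
#'
#' Counts, over the patients of a stratum, how many carry each disease and
#' each unordered disease pair. A patient contributes at most once to any
#' count regardless of how many hospitalizations repeat a diagnosis; `N` is
#' the number of distinct patients retained by the stratum filter.
#'
#' @param claims Claims tibble (columns `patient_id`, `sex`, `age`,
#'   `admission_date`, `dx1`..`dx5`).
#' @param dm_type Optional filter: keep patients whose diabetes type (from
#'   their full code set) is this value (`"T1D"`, `"T2D"`, `"other"`,
#'   `"none"`).
#' @param sex Optional `"M"`/`"F"` filter.
#' @param age_min,age_max Optional inclusive age bounds.
#' @param node_level ICD digit level at which codes are merged into network
#'   nodes (3 by default; 4 or 5 keep finer detail).
#' @return An object of class `prevalence_counts`: list with `N`, a
#'   `diseases` tibble (`code`, `n`) and a `pairs` tibble
#'   (`code_i`, `code_j`, `n_ij` with `code_i < code_j`).
#' @export
count_prevalences <- function(claims, dm_type = NULL, sex = NULL,
                              age_min = NULL, age_max = NULL,
                              node_level = 3) {
  long <- claims_long(claims)
  if (!is.null(dm_type)) {
    keep <- patient_dm_type(claims) |> filter(.data$dm_type == !!dm_type)
    long <- dplyr::semi_join(long, keep, by = "patient_id")
  }
  if (!is.null(sex)) long <- filter(long, .data$sex == !!sex)
  if (!is.null(age_min)) long <- filter(long, .data$age >= age_min)
  if (!is.null(age_max)) long <- filter(long, .data$age <= age_max)
  if (nrow(long) == 0) {
    abort("No patients left in the requested stratum.",
          class = "comorbnet_empty_population_error")
  }
  per_patient <- long |>
    mutate(code = icd_truncate(.data$code, node_level)) |>
    distinct(.data$patient_id, .data$code)
  N <- dplyr::n_distinct(per_patient$patient_id)
  diseases <- count(per_patient, .data$code, name = "n")
  pairs <- inner_join(per_patient, per_patient, by = "patient_id",
                      relationship = "many-to-many") |>
    filter(.data$code.x < .data$code.y) |>
    count(code_i = .data$code.x, code_j = .data$code.y, name = "n_ij")
  structure(
    list(N = N, diseases = diseases, pairs = pairs,
         stratum = list(dm_type = dm_type, sex = sex,
                        age_min = age_min, age_max = age_max),
         node_level = node_level),
    class = "prevalence_counts"
  )
}

#' @export
print.prevalence_counts <- function(x, ...) {
  cat("<prevalence_counts> N =", x$N, "patients,",
      nrow(x$diseases), "diseases,", nrow(x$pairs), "co-occurring pairs\n")
  invisible(x)
}

#' Candidate comorbidity links with phi values
#'
#' All unordered disease pairs observed in at least one patient, with their
#' counts and phi-correlation. Pairs whose phi is undefined (a disease seen
#' in every patient of the stratum) are dropped.
#'
#' @param counts A `prevalence_counts` object from [count_prevalences()].
#' @return Tibble `code_i`, `code_j`, `n_i`, `n_j`, `n_ij`, `phi`.
#' @export
comorbidity_links <- function(counts) {
  stopifnot(inherits(counts, "prevalence_counts"))
  N <- counts$N
  prev <- counts$diseases
  counts$pairs |>
    left_join(rename(prev, code_i = "code", n_i = "n"), by = "code_i") |>
    left_join(rename(prev, code_j = "code", n_j = "n"), by = "code_j") |>
    filter(.data$n_i > 0, .data$n_i < N, .data$n_j > 0, .data$n_j < N) |>
    mutate(phi = phi_correlation(N, .data$n_i, .data$n_j, .data$n_ij)) |>
    arrange(desc(.data$phi), .data$code_i, .data$code_j)
}

#' Build a phenotypic disease network
#'
#' Ranks all candidate comorbidity links by phi (descending) and keeps the
#' top `threshold_fraction` of them -- `ceiling(fraction * n_candidates)`
#' links, extended through ties at the cutoff value -- together with their
#' endpoint diseases.
#'
#' @param counts A `prevalence_counts` object.
#' @param threshold_fraction Fraction of ranked candidate links retained
#'   (default 0.006, i.e. the top 0.6%).
#' @param stratum Optional label describing the population (carried into
#'   the result for printing/plotting).
#' @return An object of class `pdn` with `nodes` (code, category, n),
#'   `links` (code_i, code_j, n_ij, phi), the candidate count and cutoff.
#' @export
build_pdn <- function(counts, threshold_fraction = 0.006, stratum = NULL) {
  stopifnot(inherits(counts, "prevalence_counts"))
  if (!(threshold_fraction > 0 && threshold_fraction <= 1)) {
    abort("threshold_fraction must be in (0, 1].",
          class = "comorbnet_validation_error")
  }
  cand <- comorbidity_links(counts)
  if (nrow(cand) == 0) {
    warn("No candidate comorbidity links; returning an empty PDN.")
    links <- cand
    cutoff <- NA_real_
  } else {
    k <- ceiling(threshold_fraction * nrow(cand))
    cutoff <- sort(cand$phi, decreasing = TRUE)[k]
    links <- filter(cand, .data$phi >= cutoff)
  }
  nodes <- tibble(code = union(links$code_i, links$code_j)) |>
    left_join(rename(counts$diseases, n = "n"), by = "code") |>
    mutate(category = assign_category(.data$code)) |>
    arrange(.data$code)
  structure(
    list(nodes = nodes, links = select(links, "code_i", "code_j", "n_ij", "phi"),
         threshold_fraction = threshold_fraction, phi_cutoff = cutoff,
         n_candidates = nrow(cand), N = counts$N,
         stratum = stratum %||% counts$stratum),
    class = "pdn"
  )
}

#' @export
print.pdn <- function(x, ...) {
  cat(sprintf(
    "<pdn> %d nodes, %d links (top %.3g%% of %d candidate links, phi >= %.4g)\n",
    nrow(x$nodes), nrow(x$links), 100 * x$threshold_fraction,
    x$n_candidates, x$phi_cutoff
  ))
  invisible(x)
}

#' @rdname build_pdn
#' @param x A `pdn` object.
#' @param ... Unused.
#' @export
tidy.pdn <- function(x, ...) as_tibble(x$links)

#' @rdname build_pdn
#' @export
glance.pdn <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_links = nrow(x$links),
    n_candidates = x$n_candidates,
    threshold_fraction = x$threshold_fraction,
    phi_cutoff = x$phi_cutoff, n_patients = x$N
  )
}
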