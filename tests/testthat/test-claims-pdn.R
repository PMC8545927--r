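test_that("prevalence counting deduplicates patients across claims", {
  # one patient, two hospitalizations both coding 401
  claims <- claims_from_sets(list(c("401"), c("401")))
  claims$patient_id <- "P001"
  cnt <- count_prevalences(claims)
  expect_equal(cnt$N, 1)
  expect_equal(cnt$diseases$n[cnt$diseases$code == "401"], 1L)

  # two patients: {401, 250.01} and {401}, counted at 5-digit level
  claims <- claims_from_sets(list(c("401", "250.01"), "401"))
  cnt <- count_prevalences(claims, node_level = 5)
  expect_equal(cnt$N, 2)
  expect_equal(cnt$diseases$n[cnt$diseases$code == "401"], 2L)
  expect_equal(cnt$pairs$n_ij[cnt$pairs$code_i == "25001" &
                                cnt$pairs$code_j == "401"], 1L)
})

test_that("stratum filters work and an empty stratum errors", {
  claims <- claims_from_sets(list(c("25011", "401"), c("25000", "401")))
  claims$sex <- c("M", "F")
  t1d <- count_prevalences(claims, dm_type = "T1D")
  expect_equal(t1d$N, 1)
  expect_error(count_prevalences(claims, dm_type = "none"),
               class = "comorbnet_empty_population_error")
  expect_error(count_prevalences(claims, sex = "M", age_min = 99),
               class = "comorbnet_empty_population_error")
})

test_that("counts on a synthetic cohort match the generator's ground truth", {
  spec <- default_cohort_spec(n_patients = 3000, seed = 7)
  claims <- simulate_claims(spec)
  truth <- attr(claims, "truth")
  cnt <- count_prevalences(claims)
  truth_n <- dplyr::count(dplyr::distinct(truth$assignments), code)
  for (k in seq_len(nrow(truth_n))) {
    expect_equal(
      cnt$diseases$n[cnt$diseases$code == truth_n$code[k]],
      truth_n$n[k]
    )
  }
  # pair tallies for the planted pair
  both <- dplyr::intersect(
    truth$assignments$patient_id[truth$assignments$code == "285"],
    truth$assignments$patient_id[truth$assignments$code == "585"]
  )
  expect_equal(cnt$pairs$n_ij[cnt$pairs$code_i == "285" &
                                cnt$pairs$code_j == "585"], length(both))
})

test_that("PDN thresholding keeps ceil(fraction * candidates) links plus ties", {
  # 100 candidate pairs with strictly increasing phi
  n_pairs <- 100
  diseases <- tibble::tibble(code = sprintf("%03d", 100 + seq_len(2 * n_pairs)),
                             n = 150L)
  pairs <- tibble::tibble(
    code_i = diseases$code[2 * seq_len(n_pairs) - 1],
    code_j = diseases$code[2 * seq_len(n_pairs)],
    n_ij = seq_len(n_pairs)
  )
  cnt <- make_counts(10000, diseases, pairs)
  pdn <- build_pdn(cnt, threshold_fraction = 0.006)
  expect_equal(nrow(pdn$links), 1L)           # ceil(0.6) = 1
  expect_equal(pdn$links$n_ij, n_pairs)       # the strongest pair
  expect_equal(nrow(pdn$nodes), 2L)

  # all-equal phi: tie extension keeps everything
  pairs$n_ij <- 30L
  pdn_tie <- build_pdn(make_counts(10000, diseases, pairs), 0.006)
  expect_equal(nrow(pdn_tie$links), n_pairs)
})

test_that("PDN retention is monotone in the threshold and correctly ranked", {
  set.seed(42)
  n_d <- 40
  diseases <- tibble::tibble(code = sprintf("%03d", 100 + seq_len(n_d)),
                             n = sample(50:400, n_d, replace = TRUE))
  pairs <- t(combn(diseases$code, 2))
  keep <- sample(nrow(pairs), 150)
  pairs <- tibble::tibble(code_i = pairs[keep, 1], code_j = pairs[keep, 2])
  nmax <- pmin(diseases$n[match(pairs$code_i, diseases$code)],
               diseases$n[match(pairs$code_j, diseases$code)])
  pairs$n_ij <- vapply(nmax, function(m) sample(m, 1), 1L)
  cnt <- make_counts(5000, diseases, pairs)

  cand <- comorbidity_links(cnt)
  for (f in c(0.05, 0.2, 0.5)) {
    pdn <- build_pdn(cnt, f)
    retained <- with(pdn$links, paste(code_i, code_j))
    not_retained <- dplyr::anti_join(cand, pdn$links,
                                     by = c("code_i", "code_j"))
    expect_gte(nrow(pdn$links), ceiling(f * nrow(cand)))
    if (nrow(not_retained) > 0) {
      expect_true(min(pdn$links$phi) >= max(not_retained$phi))
    }
  }
  small <- build_pdn(cnt, 0.1)$links
  large <- build_pdn(cnt, 0.4)$links
  expect_equal(nrow(dplyr::anti_join(small, large,
                                     by = c("code_i", "code_j"))), 0L)
})

test_that("PDN construction is invariant to claim record order", {
  spec <- default_cohort_spec(n_patients = 1500, seed = 3)
  claims <- simulate_claims(spec)
  shuffled <- claims[sample(nrow(claims)), ]
  p1 <- build_pdn(count_prevalences(claims), 0.05)
  p2 <- build_pdn(count_prevalences(shuffled), 0.05)
  expect_equal(p1$links, p2$links)
  expect_equal(p1$nodes, p2$nodes)
})

test_that("an empty candidate set yields an empty PDN with a warning", {
  cnt <- make_counts(100, tibble::tibble(code = "401", n = 10L),
                     tibble::tibble(code_i = character(),
                                    code_j = character(),
                                    n_ij = integer()))
  expect_warning(pdn <- build_pdn(cnt), "empty PDN")
  expect_equal(nrow(pdn$links), 0L)
  expect_equal(nrow(pdn$nodes), 0L)
})
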