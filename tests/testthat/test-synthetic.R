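test_that("cohort specs are validated, including Frechet bounds", {
  d <- tibble::tibble(code = c("401", "285"), prevalence = c(0.05, 0.05))
  # phi = -0.9 at 5%/5% would imply a negative joint probability
  expect_error(
    cohort_spec(100, d, tibble::tibble(code_i = "401", code_j = "285",
                                       target_phi = -0.9)),
    class = "comorbnet_infeasible_pair_error"
  )
  expect_error(
    cohort_spec(100, tibble::tibble(code = "401", prevalence = 1.2)),
    class = "comorbnet_validation_error"
  )
  expect_error(
    cohort_spec(100, d, tibble::tibble(code_i = "401", code_j = "999",
                                       target_phi = 0.1)),
    class = "comorbnet_validation_error"
  )
  expect_error(
    cohort_spec(100, d, dm_type_mix = c(T1D = 0.5, T2D = 0.4, other = 0.2)),
    class = "comorbnet_validation_error"
  )
  expect_s3_class(
    cohort_spec(100, d, tibble::tibble(code_i = "401", code_j = "285",
                                       target_phi = 0.3)),
    "cohort_spec"
  )
})

test_that("claims tables respect the schema and are seed-deterministic", {
  spec <- default_cohort_spec(n_patients = 800, seed = 5)
  c1 <- simulate_claims(spec)
  c2 <- simulate_claims(default_cohort_spec(n_patients = 800, seed = 5))
  attr(c1, "truth") <- attr(c2, "truth") <- NULL
  expect_identical(c1, c2)

  c3 <- simulate_claims(default_cohort_spec(n_patients = 800, seed = 6))
  attr(c3, "truth") <- NULL
  expect_false(identical(c1, c3))

  expect_named(c1, c("patient_id", "sex", "age", "admission_date",
                     paste0("dx", 1:5)))
  # every claim carries 1-5 codes, dx1 never empty
  expect_true(all(!is.na(c1$dx1)))
  n_codes <- rowSums(!is.na(c1[paste0("dx", 1:5)]))
  expect_true(all(n_codes >= 1 & n_codes <= 5))
  # at most 3 claims per patient here (no patient carries > 15 codes)
  expect_lte(max(table(c1$patient_id)), 3)
  expect_true(all(c1$sex %in% c("M", "F")))
  expect_true(all(c1$age >= 1 & c1$age <= 99))
  expect_true(all(c1$admission_date >= as.Date("2002-01-01") &
                    c1$admission_date <= as.Date("2008-12-31")))
})

test_that("diabetes typing codes realize the requested mix", {
  d <- tibble::tibble(code = "401", prevalence = 0.1)
  spec <- cohort_spec(6000, d, dm_type_mix = c(T1D = 0.3, T2D = 0.6,
                                               other = 0.1), seed = 2)
  claims <- simulate_claims(spec)
  truth <- attr(claims, "truth")
  typed <- patient_dm_type(claims)
  joined <- dplyr::inner_join(typed, truth$dm, by = "patient_id")
  expect_true(all(joined$dm_type.x == joined$dm_type.y))
  mix <- prop.table(table(joined$dm_type.x))
  expect_lt(abs(mix[["T1D"]] - 0.3), 0.03)
  expect_lt(abs(mix[["T2D"]] - 0.6), 0.03)
})

test_that("unplanted disease pairs are uncorrelated", {
  d <- tibble::tibble(code = c("401", "285", "272"),
                      prevalence = c(0.10, 0.15, 0.08))
  spec <- cohort_spec(20000, d, seed = 9)
  claims <- simulate_claims(spec)
  cnt <- count_prevalences(claims)
  links <- comorbidity_links(cnt)
  bg <- links[links$code_i %in% d$code & links$code_j %in% d$code, ]
  expect_true(all(abs(bg$phi) < 4 / sqrt(20000)))
})

test_that("planted phi is recovered from the generated claims", {
  d <- tibble::tibble(code = c("401", "285"), prevalence = c(0.1, 0.1))
  pp <- tibble::tibble(code_i = "401", code_j = "285", target_phi = 0.3)
  spec <- cohort_spec(50000, d, pp, seed = 13)
  claims <- simulate_claims(spec)
  cnt <- count_prevalences(claims)
  link <- comorbidity_links(cnt)
  row <- link[link$code_i == "285" & link$code_j == "401", ]
  expect_lt(abs(row$phi - 0.3), 0.02)
  # marginal prevalences near their specification
  n401 <- cnt$diseases$n[cnt$diseases$code == "401"]
  expect_equal(n401 / cnt$N, 0.1, tolerance = 0.1)
})

test_that("the correlated-Bernoulli joint frequency converges to p_ij", {
  p_i <- 0.1; p_j <- 0.2; phi <- 0.25
  p_ij <- p_i * p_j + phi * sqrt(p_i * (1 - p_i) * p_j * (1 - p_j))
  d <- tibble::tibble(code = c("401", "285"), prevalence = c(p_i, p_j))
  pp <- tibble::tibble(code_i = "401", code_j = "285", target_phi = phi)
  hits <- 0L
  for (seed in 1:10) {
    claims <- simulate_claims(cohort_spec(20000, d, pp, seed = seed))
    cnt <- count_prevalences(claims)
    pair <- cnt$pairs[cnt$pairs$code_i == "285" & cnt$pairs$code_j == "401", ]
    err <- abs(pair$n_ij / cnt$N - p_ij)
    if (err < 4 * sqrt(p_ij * (1 - p_ij) / 20000)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("planted modular graphs are connected, deterministic and bridged", {
  spec <- planted_graph_spec(4, 6, 2, 0.5, seed = 21)
  g1 <- simulate_planted_graph(spec)
  g2 <- simulate_planted_graph(spec)
  expect_identical(igraph::as_edgelist(g1$graph),
                   igraph::as_edgelist(g2$graph))
  expect_true(igraph::is_connected(g1$graph))
  # every connector touches >= 2 modules
  for (conn in g1$connectors) {
    nb <- igraph::neighbors(g1$graph, conn)$name
    mods <- unique(sub("_.*$", "", nb))
    expect_gte(length(mods), 2)
  }
  expect_error(planted_graph_spec(1, 5, 1), class = "comorbnet_validation_error")
  expect_error(planted_graph_spec(2, 5, 1, 0), class = "comorbnet_validation_error")
})

test_that("with complete modules the single connector has top betweenness", {
  g <- simulate_planted_graph(planted_graph_spec(2, 5, 1, 1.0, seed = 1))
  cent <- graph_centralities(g$graph)
  expect_equal(cent$node[1], "C01")
  expect_gt(cent$betweenness[1], max(cent$betweenness[-1]))
})

test_that("random bipartite networks honor edge_prob and the seed", {
  full <- simulate_bipartite(5, 7, 1, seed = 1)
  deg <- bipartite_degrees(full)
  expect_true(all(deg$degree[deg$side == "protein"] == 7))
  empty <- simulate_bipartite(5, 7, 0, seed = 1)
  expect_equal(nrow(empty$edges), 0L)
  expect_length(empty$proteins, 5)      # isolated nodes retained

  b1 <- simulate_bipartite(20, 15, 0.3, seed = 8)
  b2 <- simulate_bipartite(20, 15, 0.3, seed = 8)
  expect_identical(b1$edges, b2$edges)
  expect_false(any(duplicated(b1$edges)))
  # edge count inside the central 99% binomial interval around 90
  ci <- qbinom(c(0.005, 0.995), 300, 0.3)
  expect_gte(nrow(b1$edges), ci[1])
  expect_lte(nrow(b1$edges), ci[2])
})
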