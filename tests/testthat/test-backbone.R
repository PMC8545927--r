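# The published centrality table of the interactome giant component:
# 46 proteins (top 20% betweenness of 230 nodes) with DC/BC/CC columns.
table2_records <- function() {
  dplyr::rename(load_fixture("table2"), node = "protein")
}

# value cutoffs printed alongside that table (top 10% of the 230-node
# giant component): hubs DC >= 12, bottlenecks BC >= 0.0344
published_cfg <- threshold_config(hub_min_degree = 12,
                                  bottleneck_min_bc = 0.0344)

test_that("backbone extraction keeps ceil(fraction * n) nodes plus ties", {
  g <- simulate_planted_graph(planted_graph_spec(2, 5, 1, 1.0, seed = 4))$graph
  b <- extract_backbone(g, cfg = threshold_config(backbone_fraction = 0.2))
  expect_equal(nrow(b$records), ceiling(0.2 * igraph::vcount(g)))
  expect_true(all(b$records$node %in% igraph::V(g)$name))
  # induced edges only
  expect_true(all(igraph::as_edgelist(b$graph) %in% b$records$node))

  # all betweenness equal (complete graph): tie extension keeps everything
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  ball <- extract_backbone(k5, cfg = threshold_config(backbone_fraction = 0.2))
  expect_equal(nrow(ball$records), 5L)
})

test_that("planted connectors land inside the backbone", {
  for (seed in 1:5) {
    pg <- simulate_planted_graph(planted_graph_spec(3, 6, 1, 0.7, seed = seed))
    b <- extract_backbone(pg$graph, cfg = threshold_config(backbone_fraction = 0.2))
    expect_true(all(pg$connectors %in% b$records$node))
  }
})

test_that("role classification reproduces the published examples", {
  roles <- classify_roles(table2_records(), published_cfg)
  get <- function(p) roles$role[roles$node == p]
  expect_equal(get("CASP3"), "date-hub")   # DC 45, BC 0.2198
  expect_equal(get("AGT"), "nonhub-bottleneck")  # DC 11 < 12, BC 0.0666
  expect_equal(get("UBB"), "party-hub")    # DC 30, BC 0.0289 < 0.0344
  expect_equal(get("IL16"), "other")       # DC 2, BC 0.0206
  # the 13 proteins listed as date-hubs all classify as date-hubs
  listed <- c("CASP3", "TGFB1", "SRC", "CASP8", "UBC", "EGFR", "SHC1",
              "IGF1R", "CBL", "PIK3R1", "LCK", "TNF", "FYN")
  expect_true(all(roles$role[roles$node %in% listed] == "date-hub"))
  # a nonhub-bottleneck by direct rule application
  synth <- tibble::tibble(node = "X", degree = 5, betweenness = 0.05)
  expect_equal(classify_roles(synth, published_cfg)$role, "nonhub-bottleneck")
})

test_that("roles form an exhaustive, mutually exclusive partition", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    rec <- tibble::tibble(node = paste0("p", seq_len(n)),
                          degree = sample(0:50, n, replace = TRUE),
                          betweenness = runif(n))
    roles <- classify_roles(rec)
    expect_true(all(roles$role %in% c("date-hub", "party-hub",
                                      "nonhub-bottleneck", "other")))
    expect_equal(roles$role == "date-hub", roles$is_hub & roles$is_bottleneck)
    expect_equal(roles$role == "party-hub", roles$is_hub & !roles$is_bottleneck)
    expect_equal(roles$role == "nonhub-bottleneck",
                 !roles$is_hub & roles$is_bottleneck)
    # scale invariance of betweenness
    scaled <- dplyr::mutate(rec, betweenness = betweenness * 7.3)
    expect_equal(classify_roles(scaled)$role, roles$role)
    # bottlenecks nest inside the backbone when fractions align
    bk_cut <- sort(rec$betweenness, decreasing = TRUE)[ceiling(0.2 * n)]
    backbone_nodes <- rec$node[rec$betweenness >= bk_cut]
    expect_true(all(roles$node[roles$is_bottleneck] %in% backbone_nodes))
  }
})

test_that("backbone summary reproduces the published averages", {
  s <- summarize_backbone(table2_records())
  expect_equal(s$n_nodes, 46L)
  expect_equal(s$mean_degree, 15.78261, tolerance = 1e-6)
  expect_lt(abs(s$mean_betweenness - 0.045287), 1e-6)
  expect_equal(s$mean_closeness, 0.329266, tolerance = 1e-5)
  # order property and the single-node identity
  expect_lte(s$mean_degree, max(table2_records()$degree))
  one <- summarize_backbone(table2_records()[1, ])
  expect_equal(one$mean_degree, 45)
  expect_equal(one$mean_betweenness, 0.219802)
})

test_that("threshold configs are validated", {
  expect_error(threshold_config(backbone_fraction = 0),
               class = "comorbnet_validation_error")
  expect_error(threshold_config(hub_fraction = 1.5),
               class = "comorbnet_validation_error")
  g <- igraph::make_full_graph(4)
  igraph::V(g)$name <- letters[1:4]
  wrong <- tibble::tibble(node = c("a", "b"), degree = 1,
                          betweenness = 0.1, closeness = 0.5)
  expect_error(extract_backbone(g, records = wrong),
               class = "comorbnet_validation_error")
})
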