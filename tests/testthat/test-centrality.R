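test_that("path-graph centralities match hand computation", {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["b", "c"] <- W["c", "b"] <- 0.5
  ct <- centrality(as_network(W))
  expect_equal(ct$betweenness[ct$node == "b"], 1)
  expect_equal(ct$betweenness[ct$node %in% c("a", "c")], c(0, 0))
  expect_equal(ct$strength[ct$node == "b"], 1)
  # harmonic closeness of a: 1/d(a,b) + 1/d(a,c) = 0.5 + 0.25
  expect_equal(ct$closeness[ct$node == "a"], 0.75)
})

test_that("expected influence carries sign while strength does not", {
  W <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W["a", "b"] <- W["b", "a"] <- -0.2
  W["a", "c"] <- W["c", "a"] <- 0.2
  ct <- centrality(as_network(W))
  expect_equal(ct$strength[ct$node == "a"], 0.4)
  expect_equal(ct$expected_influence[ct$node == "a"], 0)
})

test_that("all-zero networks yield zero centralities without error", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ct <- centrality(as_network(W))
  expect_true(all(ct$strength == 0))
  expect_true(all(ct$closeness == 0))
  expect_true(all(ct$betweenness == 0))
})

test_that("path centralities equal the brute-force oracle on random networks", {
  set.seed(7)
  for (r in 1:20) {
    W <- random_weight_matrix(sample(4:12, 1))
    ct <- centrality(as_network(W))
    bf <- brute_force_paths(W)
    expect_equal(ct$betweenness, bf$betweenness, tolerance = 1e-9)
    expect_equal(ct$closeness, bf$closeness, tolerance = 1e-9)
    expect_equal(ct$strength, unname(rowSums(abs(W))))
    expect_equal(ct$expected_influence, unname(rowSums(W)))
  }
})

test_that("adding a positive edge never decreases endpoint strength", {
  set.seed(11)
  for (r in 1:10) {
    W <- random_weight_matrix(6)
    z <- which(upper.tri(W) & W == 0, arr.ind = TRUE)
    if (!nrow(z)) next
    W2 <- W
    W2[z[1, 1], z[1, 2]] <- W2[z[1, 2], z[1, 1]] <- 0.05
    s1 <- centrality(as_network(W))$strength
    s2 <- centrality(as_network(W2))$strength
    expect_true(all(s2 >= s1 - 1e-12))
  }
})

test_that("proportional deviation matches hand values and averages to zero", {
  expect_equal(proportional_deviation(c(1, 1, 1)), c(0, 0, 0))
  expect_equal(proportional_deviation(c(1.22, 1, 0.78)), c(22, 0, -22))
  set.seed(2)
  v <- runif(9, 0.5, 2)
  expect_lt(abs(mean(proportional_deviation(v))), 1e-10)
  expect_error(proportional_deviation(c(-1, 1)), "zero mean")
})

test_that("bridge report extracts only suicide-incident edges", {
  co <- sample_cohort(homogeneous_config(1500, 2))
  part <- detect_communities(estimate_network(co$items),
                             catalog = panss_catalog())
  sc <- aggregate_clusters(co, part, include_ideation = TRUE)
  net <- suicide_network(sc)
  br <- bridge_report(net)
  expect_setequal(br$target, setdiff(net$nodes, "SUI"))
  expect_equal(br$weight[br$target == "DST"], net$weights["DST", "SUI"])
  net_nosui <- estimate_network(sc[, setdiff(colnames(sc), "SUI")])
  expect_error(bridge_report(net_nosui), "no SUI node")
})

test_that("target selection scores and tie-breaks as specified", {
  ctl <- panss_catalog()
  flat <- data.frame(node = ctl$codes, strength = 1, expected_influence = 1,
                     closeness = 1, betweenness = 0,
                     strength_dev = 0, expected_influence_dev = 0,
                     closeness_dev = 0, betweenness_dev = 0)
  cl_flat <- data.frame(node = c(sort(unique(ctl$domain_of)), "SUI"),
                        strength = 1, expected_influence = 1, closeness = 1,
                        betweenness = 0, strength_dev = 0,
                        expected_influence_dev = 0, closeness_dev = 0,
                        betweenness_dev = 0)
  no_bridge <- data.frame(target = sort(unique(ctl$domain_of)), weight = 0,
                          lower = NA, upper = NA, p_fdr = 1,
                          significant = FALSE)
  tg <- select_targets(flat, cl_flat, no_bridge, ctl)
  expect_true(all(tg$score == 0))
  expect_identical(tg$domain, sort(unique(ctl$domain_of)))

  # a significant positive bridge outranks below-average centrality
  below <- flat
  below$strength_dev <- -5
  below$expected_influence_dev <- -5
  bridged <- no_bridge
  bridged$weight[bridged$target == "NEG"] <- 0.3
  bridged$significant[bridged$target == "NEG"] <- TRUE
  tg2 <- select_targets(below, cl_flat, bridged, ctl)
  expect_identical(tg2$domain[1], "NEG")
  expect_equal(tg2$score[1], 3)

  # invariance to node order permutation
  set.seed(4)
  perm <- sample(nrow(flat))
  tg3 <- select_targets(flat[perm, ], cl_flat, bridged, ctl)
  tg3b <- select_targets(flat, cl_flat, bridged, ctl)
  expect_identical(tg3$domain, tg3b$domain)
  expect_identical(tg3$score, tg3b$score)
})

test_that("the planted generator selects Distress as the leading target", {
  ctl <- panss_catalog()
  co <- sample_cohort(cohort_config(n = 2000, seed = 2))
  net <- estimate_network(co$items)
  part <- detect_communities(net, catalog = ctl)
  sc <- aggregate_clusters(co, part, include_ideation = TRUE)
  inf <- bootstrap_edge_ci(sc, B = 300, seed = 2)
  sn <- suicide_network(sc)
  tg <- select_targets(centrality(net), centrality(sn),
                       bridge_report(sn, inf), ctl)
  expect_identical(tg$domain[1], "DST")
})
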