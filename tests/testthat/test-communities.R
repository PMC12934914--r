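test_that("walktrap recovers planted blocks and degenerate structures", {
  ctl <- panss_catalog()
  # exact planted five-block matrix (within 0.3, between 0)
  P <- matrix(0, 30, 30, dimnames = list(ctl$codes, ctl$codes))
  for (d in unique(ctl$domain_of)) {
    mem <- domain_items(ctl, d)
    P[mem, mem] <- 0.3
  }
  diag(P) <- 0
  part <- detect_communities(as_network(P), catalog = ctl)
  expect_length(part$labels, 5)
  expect_equal(ari(part$assignment[ctl$codes], ctl$domain_of[ctl$codes]), 1)
  expect_setequal(unname(part$labels), c("POS", "COG", "HOS", "DST", "NEG"))

  # equal-weight clique: one community
  K <- matrix(0.4, 6, 6, dimnames = list(paste0("x", 1:6), paste0("x", 1:6)))
  diag(K) <- 0
  expect_length(detect_communities(as_network(K))$labels, 1)

  # empty network: communities undefined
  expect_error(detect_communities(as_network(K * 0)), "no edges")

  # partition determinism
  part2 <- detect_communities(as_network(P), catalog = ctl)
  expect_identical(part$assignment, part2$assignment)
})

test_that("isolated nodes become singleton communities", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W["a", "b"] <- W["b", "a"] <- 0.5
  part <- detect_communities(as_network(W))
  expect_length(unique(part$assignment), 3)
  expect_equal(part$assignment[["a"]], part$assignment[["b"]])
})

test_that("cluster aggregation averages member items and conserves totals", {
  ctl <- panss_catalog()
  # a well-formed partition: ids 1..5 labeled by domain
  ids <- stats::setNames(as.integer(factor(ctl$domain_of)), ctl$codes)
  labels <- stats::setNames(levels(factor(ctl$domain_of)),
                            seq_along(levels(factor(ctl$domain_of))))
  part <- manual_partition(ids, labels)

  items <- matrix(1, 2, 30, dimnames = list(NULL, ctl$codes))
  items[2, c("G2", "G3", "G4", "G6")] <- c(2, 3, 4, 3)
  sc <- aggregate_clusters(list(items = items, ideation = c(0L, 2L)), part)
  expect_true(all(sc[1, ] == 1))
  expect_equal(unname(sc[2, "DST"]), 3)

  # conservation: sum over domains of size * mean equals the item total
  co <- sample_cohort(cohort_config(n = 30, seed = 8))
  sc2 <- aggregate_clusters(co, part)
  sizes <- table(ctl$domain_of)[colnames(sc2)]
  expect_equal(as.numeric(sc2 %*% as.numeric(sizes)),
               unname(rowSums(co$items)))

  sc3 <- aggregate_clusters(co, part, include_ideation = TRUE)
  expect_identical(colnames(sc3)[ncol(sc3)], "SUI")
  expect_equal(sc3[, "SUI"], as.numeric(co$ideation))
})

test_that("suicide network has K+1 nodes with SUI last and finds the bridge", {
  clean <- 0
  for (sd in 14:18) {
    co <- sample_cohort(homogeneous_config(2000, sd))
    part <- detect_communities(estimate_network(co$items),
                               catalog = panss_catalog())
    sc <- aggregate_clusters(co, part, include_ideation = TRUE)
    net <- suicide_network(sc)
    expect_length(net$nodes, 6)
    expect_identical(net$nodes[6], "SUI")
    expect_gt(net$weights["DST", "SUI"], 0.5)
    others <- setdiff(net$nodes, c("DST", "SUI"))
    # spurious suicide edges are at most estimation noise
    expect_lt(max(abs(net$weights[others, "SUI"])), 0.05)
    if (all(net$weights[others, "SUI"] == 0)) clean <- clean + 1
    if (sd == 14) expect_error(suicide_network(sc[, 1:5]), "SUI")
  }
  # the planted bridge is usually the *only* suicide edge
  expect_gte(clean, 3)
})

test_that("shuffled ideation disconnects the suicide node", {
  disconnected <- 0
  for (sd in 1:5) {
    co <- sample_cohort(homogeneous_config(1500, 30 + sd))
    part <- detect_communities(estimate_network(co$items),
                               catalog = panss_catalog())
    set.seed(sd)
    co$ideation <- sample(co$ideation)
    sc <- aggregate_clusters(co, part, include_ideation = TRUE)
    net <- suicide_network(sc)
    disconnected <- disconnected + all(net$weights[, "SUI"] == 0)
  }
  expect_gte(disconnected, 4)
})

test_that("PERMANOVA separates planted blocks and matches an external implementation", {
  ctl <- panss_catalog()
  co <- sample_cohort(cohort_config(n = 1500, seed = 3))
  part <- detect_communities(estimate_network(co$items), catalog = ctl)
  S <- correlation_matrix(co$items)$S
  pm <- permanova_clusters(S, part, n_perm = 999, seed = 1)
  expect_lte(pm$p, 0.005)
  expect_gt(pm$F, 1)

  skip_if_not_installed("vegan")
  D <- as.dist(1 - abs(S))
  groups <- factor(part$assignment[colnames(S)])
  ad <- vegan::adonis2(D ~ groups, permutations = 99)
  expect_equal(pm$F, ad$F[1], tolerance = 1e-8)
})

test_that("PERMANOVA degenerate cases follow the pseudo-F definition", {
  # equal pairwise dissimilarities: among- and within-group mean squares
  # coincide, so F = 1 and the permutation p is 1
  R <- matrix(0.5, 8, 8, dimnames = list(paste0("v", 1:8), paste0("v", 1:8)))
  diag(R) <- 1
  part <- manual_partition(stats::setNames(rep(1:2, each = 4), colnames(R)))
  pm <- permanova_clusters(R, part, n_perm = 99, seed = 1)
  expect_equal(pm$F, 1)
  expect_equal(pm$p, 1)

  # singleton communities are excluded with a warning
  part2 <- manual_partition(stats::setNames(c(1, rep(2:3, c(3, 4))),
                                            colnames(R)))
  expect_warning(permanova_clusters(R, part2, n_perm = 19, seed = 1),
                 "size-1")
})
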