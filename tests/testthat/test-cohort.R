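test_that("catalog maps all 30 items onto the five domains", {
  ctl <- panss_catalog()
  expect_length(ctl$codes, 30)
  expect_setequal(unique(ctl$domain_of), c("POS", "COG", "HOS", "DST", "NEG"))
  expect_identical(sort(domain_items(ctl, "DST")), c("G2", "G3", "G4", "G6"))
  expect_equal(sum(vapply(c("POS", "COG", "HOS", "DST", "NEG"),
                          function(d) length(domain_items(ctl, d)),
                          numeric(1))), 30)
})

test_that("planted network places blocks and bridges exactly", {
  cfg <- cohort_config()
  ctl <- panss_catalog()
  P_minus <- build_planted_network(cfg, ctl, "SA-")
  P_plus <- build_planted_network(cfg, ctl, "SA+")
  # symmetry and zero diagonal hold for any configuration
  expect_identical(P_minus, t(P_minus))
  expect_true(all(diag(P_minus) == 0))
  # planted entries survive construction exactly (default config is PD)
  expect_equal(P_plus["N2", "G2"], 0.237)
  expect_equal(P_minus["G6", "SUI"], 0.30)
  expect_equal(P_minus["N2", "G2"], 0)
  dst <- domain_items(ctl, "DST")
  expect_true(all(P_minus[dst, dst][upper.tri(diag(4))] ==
                    cfg$partial_corr_within[["DST"]]))
  # implied precision is positive definite
  expect_gt(min(eigen(pcor_to_precision(P_plus))$values), 1e-6)
})

test_that("independence configuration yields the zero network", {
  cfg <- cohort_config(
    partial_corr_within = c(POS = 0, COG = 0, HOS = 0, DST = 0, NEG = 0),
    bridge_edges = data.frame(node_a = character(0), node_b = character(0),
                              weight = numeric(0)),
    sa_bridge_edges = data.frame(node_a = character(0),
                                 node_b = character(0), weight = numeric(0)))
  P <- build_planted_network(cfg)
  expect_true(all(P == 0))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(sa_plus_fraction = 1), "sa_plus_fraction")
  expect_error(cohort_config(ideation_coeffs = list(
    thresholds = c(1, 2, 2, 3, 4), slope = 1, sa_effect = 0)),
    "strictly increasing")
  expect_error(
    cohort_config(marginal_thresholds = stats::setNames(
      rep(list(c(0, 0.1, 0.1, 0.4, 0.8, 1.2)), 30), panss_catalog()$codes)),
    "strictly increasing")
})

test_that("sampling is deterministic, prefix-stable, and in range", {
  c1 <- sample_cohort(cohort_config(n = 60, seed = 9))
  c1b <- sample_cohort(cohort_config(n = 60, seed = 9))
  c2 <- sample_cohort(cohort_config(n = 150, seed = 9))
  expect_identical(c1$items, c1b$items)
  expect_identical(c1$ideation, c1b$ideation)
  # participants are counter-indexed substreams: cohorts share a prefix
  expect_identical(c1$items, c2$items[1:60, ])
  expect_identical(c1$sa, c2$sa[1:60])
  expect_true(all(c1$items %in% 1:7))
  expect_true(all(c1$ideation %in% 0:5))
  expect_false(anyNA(c1$items))
  expect_error(sample_cohort(cohort_config(n = 5)), "too small")
})

test_that("latent draws reproduce the planted partial correlations", {
  # each stratum generator checked against its own planted matrix at
  # ~50k latent draws per stratum
  cfg <- cohort_config(n = 100000, seed = 11, sa_plus_fraction = 0.5)
  co <- sample_cohort(cfg, return_latent = TRUE)
  ctl <- panss_catalog()
  for (s in 0:1) {
    Z <- co$latent[co$sa == s, ]
    emp <- precision_to_pcor(solve(cov(Z)))
    planted <- build_planted_network(cfg, ctl, if (s == 1) "SA+" else "SA-")
    expect_lt(max(abs(emp - planted)), 0.02)
  }
})

test_that("SA strata differ in Distress and Negative severity as planted", {
  co <- sample_cohort(cohort_config(n = 2000, seed = 4))
  ctl <- panss_catalog()
  dst <- rowMeans(co$items[, domain_items(ctl, "DST")])
  neg <- rowMeans(co$items[, domain_items(ctl, "NEG")])
  t_dst <- t.test(dst[co$sa == 1], dst[co$sa == 0])
  t_neg <- t.test(neg[co$sa == 1], neg[co$sa == 0])
  expect_gt(t_dst$statistic, 3)   # SA+ more distressed
  expect_lt(t_neg$statistic, -3)  # SA+ less negative severity
})

test_that("null ideation slope breaks the Distress-ideation link", {
  co <- sample_cohort(homogeneous_config(4000, 21, ideation_slope = 0))
  dst <- rowMeans(co$items[, domain_items(panss_catalog(), "DST")])
  tert <- cut(dst, quantile(dst, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)
  means <- tapply(co$ideation, tert, mean)
  expect_lt(max(means) - min(means), 0.15)
})

test_that("cohort CSV round-trips losslessly and validates its schema", {
  co <- sample_cohort(cohort_config(n = 40, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_identical(co$items, back$items)
  expect_identical(co$ideation, back$ideation)
  expect_identical(co$sa, back$sa)

  df <- utils::read.csv(f)
  df$P4[3] <- 8L
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_cohort(f2), "row 3, column P4")

  df2 <- utils::read.csv(f)
  df2$N3 <- NULL
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, f3, row.names = FALSE)
  expect_error(read_cohort(f3), "N3")
})
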