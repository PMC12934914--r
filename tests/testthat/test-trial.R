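dst_ei <- function(ei = c(G2 = 0.5, G3 = 1, G4 = 0.25, G6 = 0.8)) {
  data.frame(node = names(ei), expected_influence = unname(ei),
             stringsAsFactors = FALSE)
}

test_that("stratified randomization balances arms within strata", {
  arm <- stratified_randomize(rep(c("SA+", "SA-"), c(10, 11)), seed = 3)
  expect_equal(sum(arm[1:10] == "intervention"), 5)
  expect_equal(sum(arm[11:21] == "intervention"), 6)  # odd: extra to intervention
  expect_error(stratified_randomize(c("a", "b", "b")), "fewer than 2")
  # assignment probability ~ 1/2 per participant
  hits <- numeric(10)
  for (s in 1:1000)
    hits <- hits + (stratified_randomize(rep("x", 10), seed = s) ==
                      "intervention")
  expect_true(all(abs(hits / 1000 - 0.5) < 0.05))
})

test_that("deactivation follows the dose formula and its invariants", {
  ctl <- panss_catalog()
  prof <- matrix(5, 3, 30, dimnames = list(NULL, ctl$codes))
  prof[2, ] <- 2
  prof[3, "G3"] <- 7

  # null dose is the identity
  expect_identical(deactivate(prof, deactivation_config(alpha = 0), dst_ei()),
                   prof)
  # full dose on the most influential item hits the scale floor
  d1 <- deactivate(prof, deactivation_config(alpha = 1), dst_ei())
  expect_equal(unname(d1[1, "G3"]), 1)
  # formula arithmetic: x = 5, alpha = 0.5, e = 0.5 -> 4
  dh <- deactivate(prof, deactivation_config(alpha = 0.5), dst_ei())
  expect_equal(unname(dh[1, "G2"]), 4)
  # non-target items are bit-identical
  non_target <- setdiff(ctl$codes, domain_items(ctl, "DST"))
  expect_identical(dh[, non_target], prof[, non_target])
  # negative expected influence is clipped, not amplified
  dneg <- deactivate(prof, deactivation_config(alpha = 1),
                     dst_ei(c(G2 = 1, G3 = 1, G4 = 1, G6 = -2)))
  expect_equal(unname(dneg[1, "G6"]), 5)
  # order preservation within an item (continuous mode)
  expect_true(all(diff(dh[c(2, 1, 3), "G3"]) >= 0))
  # mean target severity non-increasing in alpha
  means <- vapply(c(0, 0.25, 0.5, 1), function(a)
    mean(deactivate(prof, deactivation_config(alpha = a),
                    dst_ei())[, domain_items(ctl, "DST")]), numeric(1))
  expect_true(all(diff(means) <= 1e-12))
  # integer mode rounds half-up with floor 1
  di <- deactivate(prof, deactivation_config(alpha = 0.5,
                                             rounding = "integer"),
                   dst_ei())
  expect_true(all(di[, domain_items(ctl, "DST")] == round(di[, domain_items(ctl, "DST")])))
  expect_true(all(di >= 1))
  # all-nonpositive influence is refused
  expect_error(deactivate(prof, deactivation_config(alpha = 0.5),
                          dst_ei(c(G2 = 0, G3 = -1, G4 = 0, G6 = 0))),
               "no influence signal")
})

test_that("copula marginals and degenerate cases are represented exactly", {
  tp <- fit_copula(matrix(rep(c(1, 7), each = 100), ncol = 1,
                          dimnames = list(NULL, "z")))
  expect_equal(tp$cdf$z$levels, c(1, 7))
  expect_equal(tp$cdf$z$cumprob, c(0.5, 1))
  draws <- sample_controls(tp, 2000, seed = 1)
  expect_setequal(unique(as.vector(draws)), c(1, 7))
  expect_lt(abs(mean(draws == 7) - 0.5), 0.05)

  # point-mass item
  expect_warning(pm <- fit_copula(cbind(a = rep(3, 60), b = rep(1:6, 10))),
                 "point mass")
  expect_true(all(sample_controls(pm, 100, seed = 2)[, "a"] == 3))

  # comonotone and independent pairs
  set.seed(4)
  x <- sample(1:7, 400, TRUE)
  com <- fit_copula(cbind(a = x, b = pmin(x + 1, 7)))
  expect_gte(com$R["a", "b"], 0.98)
  ind <- fit_copula(cbind(a = sample(1:7, 5000, TRUE),
                          b = sample(1:7, 5000, TRUE)))
  expect_lt(abs(ind$R["a", "b"]), 0.05)
  expect_error(fit_copula(matrix(1, 10, 2)), "at least 50")
})

test_that("copula resampling preserves marginals and rank dependence", {
  co <- sample_cohort(cohort_config(n = 2500, seed = 14))
  model <- fit_copula(co$items)
  xs <- sample_controls(model, 5000, seed = 5)
  expect_true(all(xs %in% 1:7))
  tv <- vapply(colnames(co$items), function(j) {
    p1 <- ideation_frequencies(co$items[, j], 1:7)
    p2 <- ideation_frequencies(xs[, j], 1:7)
    sum(abs(p1 - p2)) / 2
  }, numeric(1))
  expect_lt(max(tv), 0.05)
  d <- abs(cor(co$items, method = "spearman") - cor(xs, method = "spearman"))
  expect_lt(max(d), 0.09)
})

test_that("the emulated trial is reproducible and structurally sound", {
  co <- sample_cohort(cohort_config(n = 200, seed = 6))
  ei <- centrality(estimate_network(co$items))
  t1 <- run_trial(co, ei, deactivation_config(alpha = 0.5), seed = 11)
  t2 <- run_trial(co, ei, deactivation_config(alpha = 0.5), seed = 11)
  expect_identical(t1$t1, t2$t1)
  expect_identical(t1$arm, t2$arm)
  # 1:1 within strata
  for (s in unique(t1$stratum)) {
    tab <- table(t1$arm[t1$stratum == s])
    expect_lte(abs(tab[1] - tab[2]), 1)
  }
  # profiles complete and in range
  expect_false(anyNA(t1$t1))
  expect_true(all(t1$t1 >= 1 & t1$t1 <= 7))
  # control arm stays on the ordinal scale; intervention arm may be continuous
  ctl_rows <- t1$arm == "control"
  expect_true(all(t1$t1[ctl_rows, ] == round(t1$t1[ctl_rows, ])))
})
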