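#' Compare predicted ideation between trial arms
#'
#' Two-sided Wilcoxon-Mann-Whitney test on predicted ideation levels, plus a
#' rank-biserial effect direction and level-0 ("no ideation") proportions.
#' For small arms (at most 20,000 ways of splitting the pooled sample) the
#' p-value is the exact permutation p of the U statistic, which remains
#' valid under the heavy ties of ordinal outcomes; for larger arms the
#' tie-corrected normal approximation with continuity correction is used.
#' When baseline predictions are supplied, per-arm changes in the level-0
#' proportion are reported.
#'
#' @param pred_intervention,pred_control predicted levels per arm.
#' @param baseline_intervention,baseline_control optional baseline (T0)
#'   predicted levels for the same participants.
#' @return object of class `arm_comparison`: list with `U`, `p`,
#'   `rank_biserial` (negative when the intervention arm ranks lower),
#'   `direction`, per-arm level-0 proportions and (optionally) changes.
#' @export
compare_arms <- function(pred_intervention, pred_control,
                         baseline_intervention = NULL,
                         baseline_control = NULL) {
  x <- as.numeric(pred_intervention)
  y <- as.numeric(pred_control)
  if (!length(x) || !length(y)) stop("both arms must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    p <- 1
  } else if (choose(n1 + n2, n1) <= 20000) {
    p <- wmw_exact_p(x, y)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    p <- min(1, wt$p.value)
  }
  rb <- 2 * U / (n1 * n2) - 1
  lvl0 <- function(v) mean(v == 0)
  out <- list(U = U, p = p, rank_biserial = rb,
              direction = if (rb < 0) "intervention lower" else
                if (rb > 0) "intervention higher" else "no difference",
              level0_intervention = lvl0(x), level0_control = lvl0(y))
  if (!is.null(baseline_intervention))
    out$level0_change_intervention <- lvl0(x) - lvl0(baseline_intervention)
  if (!is.null(baseline_control))
    out$level0_change_control <- lvl0(y) - lvl0(baseline_control)
  class(out) <- "arm_comparison"
  out
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon-Mann-Whitney: U = %.1f, p = %.3g (%s)\n",
              x$U, x$p, x$direction))
  invisible(x)
}

#' Exact Wilcoxon-Mann-Whitney p-value by full enumeration
#'
#' Enumerates all ways of assigning the pooled observations to the two arms
#' and returns the two-sided permutation p-value of the U statistic. Only
#' feasible for small arms; used as the exactness oracle for the normal
#' approximation.
#'
#' @param x,y the two samples (combined size at most ~20).
#' @return exact two-sided p-value.
#' @export
wmw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mid <- length(x) * length(y) / 2
  obs <- abs(u_of(seq_len(n1)) - mid)
  combs <- utils::combn(n, n1)
  stat <- abs(apply(combs, 2, u_of) - mid)
  mean(stat >= obs - 1e-9)
}

#' Standardized mean differences for covariate balance
#'
#' SMD = (mean intervention - mean control) / pooled SD, per covariate,
#' within each stratum and in the full sample. A zero pooled SD yields an
#' SMD of 0 with a warning.
#'
#' @param trial a `trial_state`.
#' @param covariates covariate names to check (subset of `age`, `sex`).
#' @return data frame with columns `stratum`, `covariate`, `smd`,
#'   `mean_intervention`, `mean_control`.
#' @export
covariate_balance <- function(trial, covariates = c("age", "sex")) {
  strata <- c(sort(unique(trial$stratum)), "all")
  rows <- list()
  for (s in strata) {
    keep <- if (s == "all") rep(TRUE, length(trial$stratum)) else
      trial$stratum == s
    for (cv in covariates) {
      v <- trial[[cv]][keep]
      a <- trial$arm[keep]
      vi <- v[a == "intervention"]; vc <- v[a == "control"]
      sp <- sqrt((stats::var(vi) + stats::var(vc)) / 2)
      if (is.na(sp) || sp == 0) {
        warning("zero pooled SD for ", cv, " in stratum ", s,
                "; SMD reported as 0")
        smd <- 0
      } else smd <- (mean(vi) - mean(vc)) / sp
      rows[[length(rows) + 1]] <- data.frame(
        stratum = s, covariate = cv, smd = smd,
        mean_intervention = mean(vi), mean_control = mean(vc),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Age-stratified sensitivity analysis of predicted ideation shifts
#'
#' Splits each suicide-attempt stratum at its median age (ties assigned to
#' the younger half) and reports, per cell and arm, the change from baseline
#' to post-intervention in the proportion predicted to have no ideation
#' (level 0). Cells with fewer than 5 participants are flagged but still
#' reported.
#'
#' @param trial a `trial_state`.
#' @param pred_t0 baseline predicted levels for all participants.
#' @param pred_t1 post-intervention predicted levels for all participants.
#' @return data frame with columns `stratum`, `age_half`, `arm`, `n`,
#'   `level0_t0`, `level0_t1`, `level0_change`, `small_cell`.
#' @export
age_stratified_sensitivity <- function(trial, pred_t0, pred_t1) {
  if (is.null(trial$age)) stop("trial has no age covariate")
  rows <- list()
  for (s in sort(unique(trial$stratum))) {
    in_s <- trial$stratum == s
    med <- stats::median(trial$age[in_s])
    half <- ifelse(trial$age <= med, "younger", "older")
    for (h in c("younger", "older")) {
      for (a in levels(trial$arm)) {
        cell <- in_s & half == h & trial$arm == a
        n <- sum(cell)
        l0_t0 <- if (n) mean(pred_t0[cell] == 0) else NA_real_
        l0_t1 <- if (n) mean(pred_t1[cell] == 0) else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          stratum = s, age_half = h, arm = a, n = n,
          level0_t0 = l0_t0, level0_t1 = l0_t1,
          level0_change = l0_t1 - l0_t0, small_cell = n < 5,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Cluster-level suicide networks before and after the emulated trial
#'
#' Re-estimates the cluster-level suicide network at baseline (observed
#' ideation) and per arm at T1, where the suicide variable is the
#' classifier's predicted ideation (no observed post-intervention ideation
#' exists in an emulated trial). Returns the networks and the edge between
#' the target domain and the suicide node per arm, optionally with bootstrap
#' confidence intervals.
#'
#' @param trial a `trial_state`.
#' @param pred_t1 predicted ideation levels at T1 for all participants.
#' @param partition a `community_partition` over the items.
#' @param target_domain domain whose suicide edge is reported (default the
#'   trial's deactivation target).
#' @param config a [glasso_config()].
#' @param boot_B bootstrap replicates for edge CIs (`NULL` skips CIs).
#' @param seed integer seed for the bootstrap.
#' @return list with `networks` (named: `t0`, `t1_intervention`,
#'   `t1_control`) and `edges` (data frame: network, weight, lower, upper).
#' @export
post_network_contrast <- function(trial, pred_t1, partition,
                                  target_domain = NULL,
                                  config = glasso_config(), boot_B = NULL,
                                  seed = 1) {
  target_domain <- target_domain %||% trial$config$target_domain
  build <- function(profiles, sui) {
    sc <- aggregate_clusters(list(items = profiles, ideation = sui),
                             partition, include_ideation = TRUE)
    sc
  }
  sets <- list(
    t0 = build(trial$t0, trial$ideation_t0),
    t1_intervention = build(
      trial$t1[trial$arm == "intervention", , drop = FALSE],
      pred_t1[trial$arm == "intervention"]),
    t1_control = build(trial$t1[trial$arm == "control", , drop = FALSE],
                       pred_t1[trial$arm == "control"]))
  networks <- lapply(names(sets), function(nm) {
    tryCatch(suicide_network(sets[[nm]], config), error = function(e) {
      warning("suicide network for ", nm, " undefined: ",
              conditionMessage(e))
      NULL
    })
  })
  names(networks) <- names(sets)
  edges <- do.call(rbind, lapply(names(networks), function(nm) {
    if (is.null(networks[[nm]]))
      return(data.frame(network = nm, weight = NA_real_, lower = NA_real_,
                        upper = NA_real_, stringsAsFactors = FALSE))
    w <- networks[[nm]]$weights[target_domain, "SUI"]
    lo <- up <- NA_real_
    if (!is.null(boot_B)) {
      inf <- bootstrap_edge_ci(sets[[nm]], B = boot_B, config = config,
                               seed = substream_seed(seed, nm))
      hit <- (inf$node_a == target_domain & inf$node_b == "SUI") |
        (inf$node_b == target_domain & inf$node_a == "SUI")
      lo <- inf$lower[hit]; up <- inf$upper[hit]
    }
    data.frame(network = nm, weight = w, lower = lo, upper = up,
               stringsAsFactors = FALSE)
  }))
  list(networks = networks, edges = edges, target_domain = target_domain)
}
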