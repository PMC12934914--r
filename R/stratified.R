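#' Fused graphical lasso settings
#'
#' @param lambda1 sparsity penalty; `NULL` (default) selects it jointly with
#'   `lambda2` by minimizing the group-size-weighted summed EBIC over a grid.
#' @param lambda2 fusion (between-group similarity) penalty; `NULL` selects.
#' @param gamma EBIC hyperparameter used during selection.
#' @param admm_rho ADMM step parameter.
#' @param tol ADMM convergence tolerance.
#' @param max_iter maximum ADMM iterations.
#' @param n_lambda1,lambda_min_ratio sparsity-penalty grid for selection.
#' @param lambda2_ratios fusion grid, as multiples of each `lambda1` value.
#' @return object of class `fused_config`.
#' @export
fused_config <- function(lambda1 = NULL, lambda2 = NULL, gamma = 0.5,
                         admm_rho = 1, tol = 1e-5, max_iter = 2000,
                         n_lambda1 = 8, lambda_min_ratio = 0.01,
                         lambda2_ratios = c(0, 0.25, 0.5, 1)) {
  stopifnot(is.null(lambda1) || lambda1 >= 0,
            is.null(lambda2) || lambda2 >= 0, tol > 0)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, gamma = gamma,
                 admm_rho = admm_rho, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_lambda1 = as.integer(n_lambda1),
                 lambda_min_ratio = lambda_min_ratio,
                 lambda2_ratios = lambda2_ratios),
            class = "fused_config")
}

#' Jointly estimate two group networks with a fused graphical lasso
#'
#' Minimizes the group-size-weighted penalized negative log-likelihood
#' `sum_g n_g (tr(S_g K_g) - logdet K_g) + lambda1 ||K_g||_1,off +
#' lambda2 ||K_1 - K_2||_1,off` by ADMM, pooling information across strata so
#' the smaller group borrows strength from the larger. When the penalties are
#' not fixed in the config they are chosen by a joint grid search minimizing
#' the summed EBIC (each group scored at its own sample size).
#'
#' @param data_by_group named list of exactly two participants x items
#'   matrices over the same items.
#' @param config a [fused_config()].
#' @return object of class `group_networks`: list with `networks` (one
#'   `ggm_network` per group), `lambda1`, `lambda2`, and `diagnostics`.
#' @export
fused_glasso <- function(data_by_group, config = fused_config()) {
  if (length(data_by_group) != 2)
    stop("fused_glasso is implemented for exactly 2 groups")
  if (is.null(names(data_by_group)))
    names(data_by_group) <- c("group1", "group2")
  cols <- lapply(data_by_group, colnames)
  if (!identical(cols[[1]], cols[[2]]))
    stop("both groups must share the same item set (same column order)")
  cms <- lapply(data_by_group, correlation_matrix)
  S <- lapply(cms, `[[`, "S")
  ns <- vapply(cms, `[[`, numeric(1), "n")
  fit_at <- function(l1, l2, warm = NULL)
    fused_glasso_cpp(S[[1]], S[[2]], ns[1], ns[2], l1, l2,
                     config$admm_rho, config$tol, config$max_iter,
                     warm = warm)
  score_of <- function(fit) {
    k1 <- fit$precision1; k2 <- fit$precision2
    ebic_score(k1, S[[1]], ns[1], config$gamma) +
      ebic_score(k2, S[[2]], ns[2], config$gamma)
  }
  if (is.null(config$lambda1) || is.null(config$lambda2)) {
    l1max <- max(ns[1] * max(abs(S[[1]][upper.tri(S[[1]])])),
                 ns[2] * max(abs(S[[2]][upper.tri(S[[2]])])))
    l1_grid <- config$lambda1 %||%
      exp(seq(log(l1max), log(l1max * config$lambda_min_ratio),
              length.out = config$n_lambda1))
    best <- NULL
    warm <- NULL
    for (l1 in l1_grid) {
      l2_grid <- sort(config$lambda2 %||% (config$lambda2_ratios * l1))
      for (l2 in l2_grid) {
        f <- fit_at(l1, l2, warm)
        warm <- list(Z1 = f$precision1, Z2 = f$precision2,
                     U1 = f$U1, U2 = f$U2)
        if (!f$converged) next  # skip unconverged grid points
        sc <- score_of(f)
        if (is.null(best) || sc < best$score)
          best <- list(fit = f, score = sc, l1 = l1, l2 = l2)
      }
    }
    if (is.null(best))
      stop("fused graphical lasso failed to converge anywhere on the ",
           "selection grid; increase max_iter or loosen tol")
    fit <- best$fit
    lambda1 <- best$l1
    lambda2 <- best$l2
  } else {
    fit <- fit_at(config$lambda1, config$lambda2)
    lambda1 <- config$lambda1
    lambda2 <- config$lambda2
  }
  if (!fit$converged)
    stop(sprintf(
      "fused graphical lasso did not converge in %d iterations ",
      config$max_iter),
      sprintf("(primal residual %.3g, dual residual %.3g)",
              fit$primal_residual, fit$dual_residual))
  nodes <- cols[[1]]
  nets <- list(
    new_ggm_network(nodes, precision_to_pcor(fit$precision1), lambda1,
                    ebic_score(fit$precision1, S[[1]], ns[1], config$gamma),
                    ns[1], precision = fit$precision1),
    new_ggm_network(nodes, precision_to_pcor(fit$precision2), lambda1,
                    ebic_score(fit$precision2, S[[2]], ns[2], config$gamma),
                    ns[2], precision = fit$precision2))
  names(nets) <- names(data_by_group)
  structure(list(networks = nets, lambda1 = lambda1, lambda2 = lambda2,
                 diagnostics = list(iterations = fit$iterations,
                                    primal_residual = fit$primal_residual,
                                    dual_residual = fit$dual_residual)),
            class = "group_networks")
}

# Global strength of a network: sum of absolute edge weights over the upper
# triangle.
global_strength <- function(net) sum(abs(upper_vec(net$weights)))

#' Permutation network comparison test
#'
#' Tests whether two groups differ in network structure. Observed statistics
#' are the absolute difference in global strength (sum of absolute edge
#' weights) and the maximum absolute edge difference; the null distribution
#' is obtained by permuting group labels over the pooled (canonically
#' ordered) rows and re-estimating both networks. P-values use the add-one
#' convention.
#'
#' @param dataA,dataB participants x items matrices over the same items.
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed.
#' @param config a [glasso_config()] used for every network estimation.
#' @return object of class `nct_result`: list with `p_global_strength`,
#'   `p_structure`, `observed` (the two statistics), `n_perm`, `seed`.
#' @export
network_comparison_test <- function(dataA, dataB, n_perm = 1000, seed = 1,
                                    config = glasso_config()) {
  if (n_perm < 100)
    stop("n_perm = ", n_perm, " is too few permutations; use >= 100")
  if (!identical(colnames(dataA), colnames(dataB)))
    stop("both datasets must share the same items")
  statpair <- function(xa, xb) {
    na <- estimate_network(xa, config)
    nb <- estimate_network(xb, config)
    c(strength = abs(global_strength(na) - global_strength(nb)),
      structure = max(abs(na$weights - nb$weights)))
  }
  obs <- statpair(dataA, dataB)
  pooled <- rbind(as.matrix(dataA), as.matrix(dataB))
  # canonical row order makes the permutation null invariant to which group
  # is passed first (for equal group sizes)
  ord <- do.call(order, as.data.frame(pooled))
  pooled <- pooled[ord, , drop = FALSE]
  nA <- nrow(dataA)
  n <- nrow(pooled)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  exceed <- c(strength = 0L, structure = 0L)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, nA)
    stat_b <- tryCatch(
      statpair(pooled[idx, , drop = FALSE], pooled[-idx, , drop = FALSE]),
      error = function(e) c(strength = Inf, structure = Inf))
    exceed <- exceed + (stat_b >= obs)
  }
  structure(list(
    p_global_strength = unname((1 + exceed["strength"]) / (1 + n_perm)),
    p_structure = unname((1 + exceed["structure"]) / (1 + n_perm)),
    observed = obs, n_perm = n_perm, seed = seed),
    class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat(sprintf(
    "network comparison test (%d permutations):\n", x$n_perm),
    sprintf("  global strength diff = %.3f, p = %.4f\n",
            x$observed["strength"], x$p_global_strength),
    sprintf("  max edge diff        = %.3f, p = %.4f\n",
            x$observed["structure"], x$p_structure), sep = "")
  invisible(x)
}

#' Average within-cluster node strength
#'
#' For each domain, the mean over member nodes of the strength computed on
#' the subgraph restricted to that domain (edges leaving the domain do not
#' contribute). Singleton domains score 0 with a warning.
#'
#' @param net a `ggm_network`.
#' @param partition a `community_partition` covering the network's nodes.
#' @return named numeric vector, one entry per domain.
#' @export
within_cluster_connectivity <- function(net, partition) {
  miss <- setdiff(net$nodes, names(partition$assignment))
  miss <- setdiff(miss, "SUI")
  if (length(miss))
    stop("partition does not cover nodes: ", paste(miss, collapse = ", "))
  ids <- names(partition$labels)
  out <- vapply(ids, function(id) {
    mem <- names(partition$assignment)[partition$assignment == as.integer(id)]
    mem <- intersect(mem, net$nodes)
    if (length(mem) < 2) {
      warning("domain ", partition$labels[[id]],
              " has fewer than 2 member nodes; within-connectivity is 0")
      return(0)
    }
    sub <- net$weights[mem, mem, drop = FALSE]
    mean(rowSums(abs(sub)))
  }, numeric(1))
  stats::setNames(out, unname(partition$labels[ids]))
}

#' Cross-domain Spearman association, optionally partialling out ideation
#'
#' Spearman rank correlation between two domain scores with the asymptotic
#' t-test p-value. When a control variable is given, both domain scores are
#' rank-transformed and residualized on the (rank-transformed) control, and
#' the correlation of the residuals is reported (partial Spearman), with the
#' t approximation on n - 3 degrees of freedom.
#'
#' @param cluster_scores matrix of domain scores.
#' @param domain_a,domain_b column names to correlate.
#' @param control optional numeric vector (e.g. ideation) to partial out.
#' @return list with `rho` and `p`.
#' @export
cross_domain_association <- function(cluster_scores, domain_a, domain_b,
                                     control = NULL) {
  x <- cluster_scores[, domain_a]
  y <- cluster_scores[, domain_b]
  n <- length(x)
  if (n < 10) stop("cross-domain association needs n >= 10")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant domain score; association undefined")
  if (is.null(control)) {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    return(list(rho = unname(ct$estimate), p = ct$p.value))
  }
  if (stats::sd(control) == 0)
    stop("constant control variable; partial association undefined")
  rx <- rank(x); ry <- rank(y); rc <- rank(control)
  ex <- stats::resid(stats::lm(rx ~ rc))
  ey <- stats::resid(stats::lm(ry ~ rc))
  rho <- stats::cor(ex, ey)
  df <- n - 3
  tval <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df))
}
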