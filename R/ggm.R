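#' Graphical-lasso estimation settings
#'
#' @param gamma EBIC hyperparameter (0 = plain BIC; larger values select
#'   sparser networks). Default 0.5, the conservative convention of the
#'   EBIC-glasso literature.
#' @param n_lambdas size of the log-spaced penalty grid.
#' @param lambda_min_ratio smallest penalty as a fraction of the largest
#'   (which is the maximum absolute off-diagonal correlation).
#' @param correlation_kind `"pearson"` (default) or `"spearman"`.
#' @param rho ADMM step parameter.
#' @param tol ADMM convergence tolerance (applied to both primal and dual
#'   residuals, absolute and relative). The default 1e-5 keeps selected
#'   partial correlations within ~1e-4 of fully converged solutions.
#' @param max_iter maximum ADMM sweeps per penalty value.
#' @return object of class `glasso_config`.
#' @export
glasso_config <- function(gamma = 0.5, n_lambdas = 100,
                          lambda_min_ratio = 0.01,
                          correlation_kind = c("pearson", "spearman"),
                          rho = 1, tol = 1e-5, max_iter = 500) {
  correlation_kind <- match.arg(correlation_kind)
  stopifnot(gamma >= 0, n_lambdas >= 2,
            lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(gamma = gamma, n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio,
                 correlation_kind = correlation_kind,
                 rho = rho, tol = tol, max_iter = as.integer(max_iter)),
            class = "glasso_config")
}

#' Item correlation matrix with PSD repair
#'
#' @param items numeric matrix (participants x items) without missing values.
#' @param kind `"pearson"` or `"spearman"`.
#' @return list with `S` (symmetric, unit-diagonal, positive semi-definite
#'   correlation matrix), `n` (sample size) and `kind`.
#' @export
correlation_matrix <- function(items, kind = c("pearson", "spearman")) {
  kind <- match.arg(kind)
  items <- as.matrix(items)
  if (anyNA(items)) stop("items contain missing values")
  sds <- apply(items, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(items)[sds == 0], collapse = ", "))
  distinct <- apply(items, 2, function(v) length(unique(v)))
  if (any(distinct < 2))
    stop("items with fewer than 2 distinct values: ",
         paste(colnames(items)[distinct < 2], collapse = ", "))
  S <- stats::cor(items, method = kind)
  S <- nearest_psd(S)
  list(S = S, n = nrow(items), kind = kind)
}

new_ggm_network <- function(nodes, weights, lambda, ebic, n,
                            precision = NULL) {
  dimnames(weights) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = weights,
                 lambda_selected = lambda, ebic = ebic, n = n,
                 precision = precision),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  E <- sum(upper_vec(x$weights) != 0)
  cat(sprintf(
    "GGM network: %d nodes, %d edges (lambda = %.4g, EBIC = %.1f, n = %d)\n",
    length(x$nodes), E, x$lambda_selected, x$ebic, x$n))
  invisible(x)
}

# EBIC of a precision matrix K against correlation matrix S at sample size n:
# -2 * [n/2 (logdet K - tr(SK))] + E log n + 4 gamma E log p,
# with E the number of nonzero upper-triangle off-diagonal entries.
ebic_score <- function(K, S, n, gamma) {
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  loglik <- (n / 2) * (as.numeric(ld$modulus) - sum(S * K))
  E <- sum(upper_vec(K) != 0)
  -2 * loglik + E * log(n) + 4 * gamma * E * log(nrow(K))
}

#' EBIC-selected graphical lasso network
#'
#' Solves the l1-penalized Gaussian log-likelihood over a log-spaced penalty
#' grid (ADMM, off-diagonal penalty only) and returns the partial-correlation
#' network at the penalty minimizing the extended BIC.
#'
#' @param S correlation matrix (positive semi-definite).
#' @param n sample size behind `S`.
#' @param config a [glasso_config()].
#' @return a `ggm_network` with elements `nodes`, `weights` (partial
#'   correlations, symmetric with zero diagonal), `lambda_selected`, `ebic`,
#'   `n`, and the selected `precision` matrix. The full penalty path is
#'   attached as attribute `path` (a data frame of lambda, edge count, EBIC).
#' @export
glasso_ebic <- function(S, n, config = glasso_config()) {
  stopifnot(inherits(config, "glasso_config"))
  S <- (S + t(S)) / 2
  p <- nrow(S)
  nodes <- colnames(S) %||% paste0("V", seq_len(p))
  lmax <- max(abs(S[upper.tri(S)]), 1e-12)
  lambdas <- exp(seq(log(lmax), log(lmax * config$lambda_min_ratio),
                     length.out = config$n_lambdas))
  fit <- glasso_path_cpp(S, lambdas, config$rho, config$tol,
                         config$max_iter, n, config$gamma)
  conv <- as.logical(fit$converged)
  if (!any(conv))
    stop("graphical lasso failed to converge at every penalty value ",
         sprintf("(rho = %g, tol = %g, max_iter = %d)",
                 config$rho, config$tol, config$max_iter))
  scores <- fit$ebic
  edges <- fit$n_edges
  best <- which.min(scores)
  K <- fit$precisions[, , best]
  W <- precision_to_pcor(K)
  net <- new_ggm_network(nodes, W, lambdas[best], scores[best], n,
                         precision = K)
  attr(net, "path") <- data.frame(lambda = lambdas, n_edges = edges,
                                  ebic = scores, converged = conv)
  attr(net, "config") <- config
  net
}

#' Estimate an EBIC-glasso network straight from an item matrix
#'
#' Convenience wrapper: [correlation_matrix()] followed by [glasso_ebic()].
#'
#' @param items participants x items matrix.
#' @param config a [glasso_config()].
#' @return a `ggm_network`.
#' @export
estimate_network <- function(items, config = glasso_config()) {
  cm <- correlation_matrix(items, config$correlation_kind)
  glasso_ebic(cm$S, cm$n, config)
}

#' Bootstrap confidence intervals and FDR tests for network edges
#'
#' Nonparametric case-resampling bootstrap of the full EBIC-glasso pipeline.
#' Per-edge 95% percentile intervals (widened, if necessary, to contain the
#' full-sample point estimate so the interval and the estimate are mutually
#' coherent), sign-crossing p-values with add-one smoothing, and
#' Benjamini-Hochberg correction across the upper triangle.
#'
#' @param items participants x items matrix.
#' @param B bootstrap replicates (at least 200).
#' @param config a [glasso_config()].
#' @param seed integer seed.
#' @return object of class `edge_inference`: data frame with one row per
#'   unordered node pair and columns `node_a`, `node_b`, `estimate`, `lower`,
#'   `upper`, `p_raw`, `p_fdr`.
#' @export
bootstrap_edge_ci <- function(items, B = 500, config = glasso_config(),
                              seed = 1) {
  if (B < 200)
    stop("B = ", B, " bootstrap replicates are too few for stable 95% ",
         "intervals; use B >= 200")
  items <- as.matrix(items)
  n <- nrow(items)
  full <- estimate_network(items, config)
  pairs <- upper_pairs(full$nodes)
  est <- upper_vec(full$weights)
  boot <- matrix(NA_real_, B, length(est))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    net_b <- tryCatch(estimate_network(items[idx, , drop = FALSE], config),
                      error = function(e) NULL)
    if (!is.null(net_b)) boot[b, ] <- upper_vec(net_b$weights)
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  Bok <- nrow(boot)
  lower <- pmin(apply(boot, 2, stats::quantile, 0.025), est)
  upper <- pmax(apply(boot, 2, stats::quantile, 0.975), est)
  p_raw <- vapply(seq_along(est), function(j) {
    le <- (1 + sum(boot[, j] <= 0)) / (Bok + 1)
    ge <- (1 + sum(boot[, j] >= 0)) / (Bok + 1)
    min(1, 2 * min(le, ge))
  }, numeric(1))
  out <- cbind(pairs, data.frame(
    estimate = est, lower = lower, upper = upper,
    p_raw = p_raw, p_fdr = stats::p.adjust(p_raw, method = "BH")))
  attr(out, "B") <- Bok
  class(out) <- c("edge_inference", "data.frame")
  out
}

#' Case-dropping correlation-stability (CS) coefficient
#'
#' Re-estimates the network on subsamples with increasing fractions of
#' participants dropped and reports, per fraction, quantiles of the
#' correlation between subsample and full-sample edge weights (or node
#' strengths). The CS coefficient is the largest drop fraction whose 5th
#' percentile correlation still reaches the threshold; networks estimated as
#' empty contribute a correlation of zero.
#'
#' @param items participants x items matrix.
#' @param target `"structure"` (edge weights) or `"strength"` (node strength).
#' @param drop_grid drop fractions, all in (0, 0.75].
#' @param B subsamples per drop fraction.
#' @param correlation_threshold stability threshold (default 0.7).
#' @param probability confidence level: the CS requirement is that the
#'   `1 - probability` quantile of the correlations clears the threshold.
#' @param config a [glasso_config()].
#' @param seed integer seed.
#' @return object of class `stability_result`: list with `cs` (the CS
#'   coefficient; 0 if no fraction qualifies), `target`, and `table` (per
#'   drop fraction: evaluated flag and correlation quantiles).
#' @export
case_dropping_cs <- function(items, target = c("structure", "strength"),
                             drop_grid = seq(0.1, 0.7, by = 0.1), B = 250,
                             correlation_threshold = 0.7, probability = 0.95,
                             config = glasso_config(), seed = 1) {
  target <- match.arg(target)
  stopifnot(all(drop_grid > 0), all(drop_grid <= 0.75))
  items <- as.matrix(items)
  n <- nrow(items)
  p <- ncol(items)
  full <- estimate_network(items, config)
  stat_of <- function(net)
    if (target == "structure") upper_vec(net$weights) else
      rowSums(abs(net$weights))
  ref <- stat_of(full)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  qs <- c(1 - probability, 0.25, 0.5)
  tab <- data.frame(drop = sort(drop_grid), evaluated = FALSE,
                    q05 = NA_real_, q25 = NA_real_, q50 = NA_real_)
  for (k in seq_len(nrow(tab))) {
    m <- round((1 - tab$drop[k]) * n)
    if (m < 3 * p) {
      warning(sprintf(
        "drop fraction %.2f leaves %d cases (< 3p = %d); skipped",
        tab$drop[k], m, 3 * p))
      next
    }
    cors <- numeric(B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, m, replace = FALSE)
      net_b <- tryCatch(estimate_network(items[idx, , drop = FALSE], config),
                        error = function(e) NULL)
      if (is.null(net_b)) { cors[b] <- 0; next }
      v <- stat_of(net_b)
      r <- suppressWarnings(stats::cor(v, ref))
      cors[b] <- if (is.na(r)) 0 else r
    }
    tab$evaluated[k] <- TRUE
    tab[k, c("q05", "q25", "q50")] <- stats::quantile(cors, qs)
  }
  ok <- tab$evaluated & !is.na(tab$q05) &
    tab$q05 >= correlation_threshold
  cs <- if (any(ok)) max(tab$drop[ok]) else 0
  structure(list(cs = cs, target = target, table = tab,
                 correlation_threshold = correlation_threshold,
                 probability = probability),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("case-dropping stability (%s): CS = %.2f (threshold %.2f)\n",
              x$target, x$cs, x$correlation_threshold))
  invisible(x)
}
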