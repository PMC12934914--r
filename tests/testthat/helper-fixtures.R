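# Shared fixtures and independent oracles used across the test files.

# Adjusted Rand index between two labelings (independent of any package
# clustering code).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Cohort configuration with homogeneous strata: no SA mean shifts and no
# SA-specific planted edge, so the only cross-domain signal is the planted
# Distress-ideation bridge. Used to isolate bridge-detection properties.
homogeneous_config <- function(n, seed, ideation_slope = NULL) {
  ic <- cohort_config()$ideation_coeffs
  if (!is.null(ideation_slope)) {
    ic$slope <- ideation_slope
    if (ideation_slope == 0) {
      # a pure-noise ideation outcome whose marginal matches the default
      # cohort's observed level distribution (the default thresholds sit on
      # the scale of slope * mean-Distress and would degenerate at slope 0)
      ic$thresholds <- stats::qlogis(c(0.72, 0.85, 0.93, 0.97, 0.995))
    }
  }
  cohort_config(
    n = n, seed = seed,
    sa_bridge_edges = data.frame(node_a = character(0),
                                 node_b = character(0),
                                 weight = numeric(0)),
    sa_shift = c(POS = 0, COG = 0, HOS = 0, DST = 0, NEG = 0),
    ideation_coeffs = ic)
}

# A partition object over arbitrary node names (bypasses detection).
manual_partition <- function(assignment, labels = NULL) {
  ids <- sort(unique(assignment))
  if (is.null(labels)) labels <- stats::setNames(paste0("C", ids), ids)
  structure(list(assignment = assignment, labels = labels, modularity = NA),
            class = "community_partition")
}

# Wrap a weight matrix as a network object.
as_network <- function(W, n = 100) {
  nodes <- rownames(W) %||% paste0("V", seq_len(nrow(W)))
  dimnames(W) <- list(nodes, nodes)
  netrx:::new_ggm_network(nodes, W, lambda = 0.1, ebic = 0, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent all-pairs shortest-path oracle: Floyd-Warshall with geodesic
# counting on distances 1/|w|; returns harmonic closeness and betweenness
# with fractional credit for ties.
brute_force_paths <- function(W, tol = 1e-12) {
  p <- nrow(W)
  D <- 1 / abs(W)
  D[W == 0] <- Inf
  diag(D) <- 0
  sig <- (W != 0) * 1
  for (k in 1:p) for (i in 1:p) for (j in 1:p) {
    if (i == j || i == k || j == k) next
    alt <- D[i, k] + D[k, j]
    if (!is.finite(alt)) next
    if (alt < D[i, j] - tol) {
      D[i, j] <- alt
      sig[i, j] <- sig[i, k] * sig[k, j]
    } else if (abs(alt - D[i, j]) <= tol) {
      sig[i, j] <- sig[i, j] + sig[i, k] * sig[k, j]
    }
  }
  btw <- numeric(p)
  clo <- numeric(p)
  for (v in 1:p) {
    dv <- D[v, -v]
    clo[v] <- sum(1 / dv[is.finite(dv)])
    for (s in 1:(p - 1)) for (t in (s + 1):p) {
      if (s == v || t == v || !is.finite(D[s, t])) next
      if (abs(D[s, v] + D[v, t] - D[s, t]) <= tol)
        btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
    }
  }
  list(betweenness = btw, closeness = clo)
}

# Random sparse symmetric weight matrix for oracle tests.
random_weight_matrix <- function(p, density = 0.4) {
  W <- matrix(0, p, p)
  idx <- which(upper.tri(W))
  on <- sample(idx, max(1, round(length(idx) * density)))
  W[on] <- round(stats::runif(length(on), -0.6, 0.6), 3)
  W[on][W[on] == 0] <- 0.1
  W <- W + t(W)
  diag(W) <- 0
  dimnames(W) <- list(paste0("n", 1:p), paste0("n", 1:p))
  W
}

# Independent exact two-sided Wilcoxon-Mann-Whitney p-value computed from
# the pair-counting definition of U (x > y counts 1, ties 0.5) over every
# split of the pooled sample; deliberately a different algorithm from the
# package's rank-sum enumeration.
wmw_paircount_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mid <- n1 * (n - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - mid)
  splits <- utils::combn(n, n1)
  stat <- abs(apply(splits, 2, u_of) - mid)
  mean(stat >= obs - 1e-9)
}
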