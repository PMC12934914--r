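#' Configuration for the synthetic PANSS cohort generator
#'
#' Defines the planted latent partial-correlation structure (five
#' within-domain blocks plus cross-domain and ideation bridges), the ordinal
#' discretization of each item, the suicide-attempt stratum contrasts, and the
#' ordered-logit model generating the suicidal-ideation outcome. Defaults are
#' calibrated so that a generated cohort reproduces the summary structure of
#' published PANSS severity data: right-skewed item marginals, SA+ median
#' Distress domain score near 2.5 against 2.0 in SA-, lower Negative severity
#' in SA+, a Distress-to-ideation bridge, and a Negative-Distress cross-domain
#' edge present only in the SA+ stratum.
#'
#' @param n number of participants (default 313).
#' @param partial_corr_within named vector of within-domain latent partial
#'   correlations, one entry per domain label.
#' @param bridge_edges data frame (`node_a`, `node_b`, `weight`) of planted
#'   cross-domain / ideation partial correlations shared by both strata. The
#'   ideation node is named `"SUI"`.
#' @param sa_bridge_edges additional planted edges present only in the SA+
#'   stratum (same format).
#' @param sa_plus_fraction proportion of participants in the SA+ stratum.
#' @param sa_shift named vector of per-domain latent mean shifts (in latent
#'   standard-deviation units) applied to SA+ participants.
#' @param ideation_coeffs list with `thresholds` (5 strictly increasing
#'   ordered-logit cutpoints for levels 0-5), `slope` (on the mean Distress
#'   item score, anchored at the scale floor of 1), and `sa_effect` (SA+ main
#'   effect on the logit scale). Level 6 of the ideation scale receives zero
#'   mass by construction.
#' @param marginal_probs named list of per-domain probability vectors over
#'   levels 1-7 used to derive item discretization thresholds; all entries
#'   must be positive.
#' @param marginal_thresholds optional named list of per-item strictly
#'   increasing cutpoints (length 6) overriding `marginal_probs`.
#' @param age_dist list of log-normal age parameters per stratum.
#' @param sex_dist list of female proportions per stratum.
#' @param seed global integer seed feeding the per-participant streams.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(
    n = 313,
    partial_corr_within = c(POS = 0.10, COG = 0.09, HOS = 0.33,
                            DST = 0.28, NEG = 0.14),
    bridge_edges = data.frame(node_a = "G6", node_b = "SUI", weight = 0.30,
                              stringsAsFactors = FALSE),
    sa_bridge_edges = data.frame(node_a = "N2", node_b = "G2",
                                 weight = 0.237, stringsAsFactors = FALSE),
    sa_plus_fraction = 107 / 313,
    sa_shift = c(POS = 0.10, COG = -0.20, HOS = 0.00, DST = 0.30,
                 NEG = -0.35),
    # (DST marginal and shift jointly calibrated so the median Distress
    # domain score is ~2.5 in SA+ and ~2.0 in SA-)
    ideation_coeffs = list(
      thresholds = c(12.0, 16.5, 21.0, 25.5, 30.0),
      slope = 6,
      sa_effect = 0),
    marginal_probs = default_marginal_probs(),
    marginal_thresholds = NULL,
    age_dist = list(
      sa_plus = list(meanlog = log(32), sdlog = 0.48),
      sa_minus = list(meanlog = log(23), sdlog = 0.30)),
    sex_dist = list(p_female_sa_plus = 0.39, p_female_sa_minus = 0.25),
    seed = 1L) {
  cfg <- structure(list(
    n = as.integer(n),
    partial_corr_within = partial_corr_within,
    bridge_edges = bridge_edges,
    sa_bridge_edges = sa_bridge_edges,
    sa_plus_fraction = sa_plus_fraction,
    sa_shift = sa_shift,
    ideation_coeffs = ideation_coeffs,
    marginal_probs = marginal_probs,
    marginal_thresholds = marginal_thresholds,
    age_dist = age_dist,
    sex_dist = sex_dist,
    seed = as.integer(seed)), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Default right-skewed per-domain item marginals
#'
#' Probability mass over severity levels 1-7 for items of each domain in the
#' SA- reference stratum. Chosen so roughly 55% of item mass sits at levels
#' 1-2 and the implied median domain scores approximate published severity
#' quartiles; the SA+ latent shifts move mass through the same cutpoints.
#'
#' @return named list of length-7 probability vectors.
#' @export
default_marginal_probs <- function() {
  list(
    POS = c(0.300, 0.200, 0.170, 0.140, 0.105, 0.060, 0.025),
    COG = c(0.440, 0.250, 0.140, 0.085, 0.048, 0.026, 0.011),
    HOS = c(0.750, 0.110, 0.060, 0.040, 0.022, 0.012, 0.006),
    DST = c(0.350, 0.260, 0.170, 0.120, 0.070, 0.020, 0.010),
    NEG = c(0.420, 0.240, 0.150, 0.095, 0.055, 0.028, 0.012))
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n < 1) stop("n must be positive")
  if (!(cfg$sa_plus_fraction > 0 && cfg$sa_plus_fraction < 1))
    stop("sa_plus_fraction must lie strictly inside (0, 1)")
  pc <- cfg$partial_corr_within
  if (any(pc < 0) || any(pc >= 1))
    stop("partial_corr_within entries must lie in [0, 1)")
  thr <- cfg$ideation_coeffs$thresholds
  if (length(thr) != 5L || any(diff(thr) <= 0))
    stop("ideation thresholds must be exactly 5 strictly increasing values")
  for (be in list(cfg$bridge_edges, cfg$sa_bridge_edges)) {
    if (nrow(be) > 0 &&
        !all(c("node_a", "node_b", "weight") %in% names(be)))
      stop("bridge edge tables need columns node_a, node_b, weight")
  }
  mt <- cfg$marginal_thresholds
  if (!is.null(mt)) {
    bad <- names(mt)[vapply(mt, function(v)
      length(v) != 6L || any(diff(v) <= 0), logical(1))]
    if (length(bad))
      stop("marginal thresholds must be 6 strictly increasing cutpoints; ",
           "offending items: ", paste(bad, collapse = ", "))
  } else {
    for (d in names(cfg$marginal_probs)) {
      pr <- cfg$marginal_probs[[d]]
      if (length(pr) != 7L || any(pr <= 0) || abs(sum(pr) - 1) > 1e-8)
        stop("marginal_probs for domain ", d,
             " must be 7 positive probabilities summing to 1")
    }
  }
  invisible(cfg)
}

# Per-item discretization cutpoints on the latent N(0,1) scale, derived from
# the domain-level target marginals unless explicitly overridden.
item_thresholds <- function(cfg, catalog) {
  if (!is.null(cfg$marginal_thresholds)) {
    mt <- cfg$marginal_thresholds
    missing <- setdiff(catalog$codes, names(mt))
    if (length(missing))
      stop("marginal_thresholds missing items: ",
           paste(missing, collapse = ", "))
    return(mt[catalog$codes])
  }
  out <- lapply(catalog$codes, function(code) {
    d <- catalog$domain_of[[code]]
    stats::qnorm(cumsum(cfg$marginal_probs[[d]])[1:6])
  })
  names(out) <- catalog$codes
  out
}

#' Build the planted latent partial-correlation network
#'
#' Constructs the 31-node (30 items plus the ideation node `SUI`) latent
#' partial-correlation matrix implied by a cohort configuration: within-domain
#' entries equal the domain's `partial_corr_within`, planted bridge entries
#' are set as configured (SA+ additionally receives `sa_bridge_edges`), and
#' everything else is zero. If the implied unit-diagonal precision matrix is
#' not positive definite, a ridge is added to the diagonal in steps until the
#' smallest eigenvalue clears 1e-6 and the matrix is renormalized, so the
#' returned matrix is always a realizable partial-correlation structure.
#'
#' @param config a `cohort_config`.
#' @param catalog an `item_catalog`.
#' @param stratum `"SA-"` (default) or `"SA+"`.
#' @return symmetric 31 x 31 partial-correlation matrix with zero diagonal,
#'   rows/columns named by item code plus `"SUI"`.
#' @export
build_planted_network <- function(config, catalog = panss_catalog(),
                                  stratum = c("SA-", "SA+")) {
  stratum <- match.arg(stratum)
  validate_cohort_config(config)
  validate_catalog(catalog)
  nodes <- c(catalog$codes, "SUI")
  p <- length(nodes)
  P <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (d in names(config$partial_corr_within)) {
    mem <- domain_items(catalog, d)
    P[mem, mem] <- config$partial_corr_within[[d]]
  }
  edges <- config$bridge_edges
  if (stratum == "SA+") edges <- rbind(edges, config$sa_bridge_edges)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges$node_a[k]; b <- edges$node_b[k]
      if (!(a %in% nodes) || !(b %in% nodes))
        stop("bridge edge references unknown node: ", a, "-", b)
      P[a, b] <- P[b, a] <- edges$weight[k]
    }
  }
  diag(P) <- 0
  K <- pcor_to_precision(P)
  ridge <- 0
  step <- 0.05
  for (i in 0:100) {
    ev <- min(eigen(K + diag(ridge, p), symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev >= 1e-6) break
    if (i == 100)
      stop("planted precision matrix is not positive definite after 100 ",
           "ridge steps; reduce partial_corr_within (",
           paste(sprintf("%s=%.2f", names(config$partial_corr_within),
                         config$partial_corr_within), collapse = ", "),
           ") or the planted bridge weights")
    ridge <- ridge + step
  }
  if (ridge > 0) {
    K <- K + diag(ridge, p)
    K <- K / outer(sqrt(diag(K)), sqrt(diag(K)))
    P <- precision_to_pcor(K)
  }
  P
}
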