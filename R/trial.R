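#' Deactivation (simulated intervention) settings
#'
#' @param target_domain domain whose member items are deactivated.
#' @param alpha maximum fractional reduction between 0 and 1: the dose received by
#'   the domain's most influential item.
#' @param normalization how member items' (non-negative) expected influence
#'   is normalized into per-item doses: `"max"` (default; the most
#'   influential item gets the full dose) or `"sum"`.
#' @param rounding `"continuous"` (default) keeps fractional post-treatment
#'   severities; `"integer"` rounds half-up back to 1-7 scale levels.
#' @return object of class `deactivation_config`.
#' @export
deactivation_config <- function(target_domain = "DST", alpha = 0.5,
                                normalization = c("max", "sum"),
                                rounding = c("continuous", "integer")) {
  stopifnot(alpha >= 0, alpha <= 1)
  structure(list(target_domain = target_domain, alpha = alpha,
                 normalization = match.arg(normalization),
                 rounding = match.arg(rounding)),
            class = "deactivation_config")
}

#' Deactivate a symptom domain in proportion to expected influence
#'
#' Reduces each target-domain item toward the scale floor of 1 ("absent") in
#' proportion to its normalized expected-influence centrality: item j with
#' normalized influence `e_j` moves from `x` to `x - alpha * e_j * (x - 1)`.
#' Negative expected influence is clipped to zero (a negatively connected
#' symptom is left untouched rather than amplified). Items outside the target
#' domain are returned unchanged.
#'
#' @param profiles participants x items matrix of baseline (T0) severities.
#' @param config a [deactivation_config()].
#' @param ei a `centrality_table` computed on the item-level network
#'   containing the target domain's items.
#' @param catalog an `item_catalog`.
#' @return matrix of post-intervention (T1) severities, same shape as
#'   `profiles`; numeric in continuous mode, integer levels in rounding mode.
#' @export
deactivate <- function(profiles, config = deactivation_config(), ei,
                       catalog = panss_catalog()) {
  stopifnot(inherits(config, "deactivation_config"))
  members <- domain_items(catalog, config$target_domain)
  if (length(members) == 0)
    stop("unknown target domain: ", config$target_domain)
  miss <- setdiff(members, ei$node)
  if (length(miss))
    stop("expected-influence table is missing target items: ",
         paste(miss, collapse = ", "))
  e_raw <- pmax(0, ei$expected_influence[match(members, ei$node)])
  if (all(e_raw <= 0))
    stop("all member expected influences are <= 0 in domain ",
         config$target_domain, "; no influence signal to scale reductions by")
  denom <- if (config$normalization == "max") max(e_raw) else sum(e_raw)
  e <- e_raw / denom
  if (config$alpha == 0) return(profiles)  # exact identity, type included
  out <- profiles
  for (k in seq_along(members)) {
    x <- profiles[, members[k]]
    out[, members[k]] <- x - config$alpha * e[k] * (x - 1)
  }
  if (config$rounding == "integer")
    out[, members] <- pmax(1, floor(out[, members] + 0.5))
  out
}

#' Stratified 1:1 randomization
#'
#' Within each stratum, a random permutation split; with an odd stratum size
#' the intervention arm receives the extra participant. Deterministic given
#' the seed.
#'
#' @param stratum_labels vector of stratum labels, one per participant.
#' @param seed integer seed.
#' @return factor with levels `intervention`, `control`.
#' @export
stratified_randomize <- function(stratum_labels, seed = 1) {
  if (anyNA(stratum_labels)) stop("every participant needs a stratum label")
  arm <- character(length(stratum_labels))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (s in sort(unique(as.character(stratum_labels)))) {
    idx <- which(stratum_labels == s)
    if (length(idx) < 2)
      stop("stratum ", s, " has fewer than 2 participants")
    perm <- sample(idx)
    n_int <- ceiling(length(idx) / 2)
    arm[perm[seq_len(n_int)]] <- "intervention"
    arm[perm[-seq_len(n_int)]] <- "control"
  }
  factor(arm, levels = c("intervention", "control"))
}

#' Fit a Gaussian copula to ordinal item profiles
#'
#' Each item is transformed through its empirical CDF with mid-rank treatment
#' of ties and mapped through the standard normal quantile; the latent
#' correlation starts from the Pearson correlation of these normal scores.
#' Because mid-rank scores collapse the within-tie variation of the latent
#' variable, that raw estimate is attenuated for heavily tied ordinals, so
#' each pair is rescaled by the first-order (Hermite) attenuation factors
#' `kappa_j` implied by the item margins before the matrix is repaired to
#' positive semi-definiteness. Constant items are modeled as point masses
#' (with a warning).
#'
#' @param profiles participants x items matrix (at least `min_n` rows).
#' @param min_n refusal threshold (default 50). [run_trial()] lowers it to
#'   30, since a stratified 1:1 design at realistic cohort sizes can leave a
#'   control arm slightly under 50.
#' @return object of class `copula_model`: list with `cdf` (per item: levels
#'   and cumulative probabilities), `R` (latent correlation), `items`, `n`.
#' @export
fit_copula <- function(profiles, min_n = 50) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < min_n)
    stop("copula fitting needs at least ", min_n, " profiles; got ", n)
  items <- colnames(profiles) %||% paste0("V", seq_len(ncol(profiles)))
  colnames(profiles) <- items
  constant <- apply(profiles, 2, function(v) length(unique(v)) == 1)
  if (any(constant))
    warning("constant item(s) modeled as point masses: ",
            paste(items[constant], collapse = ", "))
  Z <- matrix(0, n, ncol(profiles))
  for (j in seq_len(ncol(profiles))) {
    if (constant[j]) next
    r <- rank(profiles[, j], ties.method = "average")
    Z[, j] <- stats::qnorm((r - 0.5) / n)
  }
  cdf <- lapply(seq_along(items), function(j) {
    tab <- table(profiles[, j])
    list(levels = as.numeric(names(tab)),
         cumprob = cumsum(as.numeric(tab)) / n)
  })
  names(cdf) <- items
  # De-attenuation: mid-rank scores collapse within-tie latent variation, so
  # their Pearson correlation understates the latent correlation. The exact
  # relationship is the Hermite series r_score(rho) =
  # sum_m rho^m lam_i^(m) lam_j^(m) / (m! sig_i sig_j), where lam^(m) are the
  # Hermite coefficients of the score step function implied by the item's
  # margins; each pair's latent correlation is recovered by inverting this
  # monotone series.
  lam <- lapply(seq_along(items), function(j) {
    if (constant[j]) return(NULL)
    hermite_score_coefs(cdf[[j]]$cumprob, m_max = 10)
  })
  R <- diag(ncol(profiles))
  ok <- which(!constant)
  if (length(ok) > 1) {
    Rs <- stats::cor(Z[, ok, drop = FALSE])
    for (a in seq_along(ok)) for (b in seq_len(a - 1)) {
      Rs[a, b] <- Rs[b, a] <-
        invert_score_correlation(Rs[a, b], lam[[ok[a]]], lam[[ok[b]]])
    }
    diag(Rs) <- 1
    R[ok, ok] <- Rs
  }
  R <- nearest_psd(R)
  dimnames(R) <- list(items, items)
  structure(list(cdf = cdf, R = R, items = items, n = n),
            class = "copula_model")
}

# Hermite coefficients lam^(m), m = 1..m_max, of the mid-rank score step
# function of an ordinal item with cumulative margins Fk, normalized by the
# score standard deviation. Uses int_a^b He_m(z) phi(z) dz =
# He_{m-1}(a) phi(a) - He_{m-1}(b) phi(b) (zero at infinite thresholds).
hermite_score_coefs <- function(Fk, m_max = 10) {
  Fk1 <- c(0, Fk[-length(Fk)])
  pk <- Fk - Fk1
  sk <- stats::qnorm((Fk1 + Fk) / 2)
  tl <- stats::qnorm(Fk1)
  tu <- stats::qnorm(Fk)
  he_phi <- function(t, m) {
    # He_m(t) * phi(t), 0 at +-Inf
    out <- numeric(length(t))
    fin <- is.finite(t)
    if (any(fin)) {
      h0 <- rep(1, sum(fin)); h1 <- t[fin]
      h <- if (m == 0) h0 else if (m == 1) h1 else {
        for (k in 2:m) { h2 <- t[fin] * h1 - (k - 1) * h0; h0 <- h1; h1 <- h2 }
        h1
      }
      out[fin] <- h * stats::dnorm(t[fin])
    }
    out
  }
  sigma <- sqrt(sum(pk * sk^2) - sum(pk * sk)^2)
  vapply(seq_len(m_max), function(m)
    sum(sk * (he_phi(tl, m - 1) - he_phi(tu, m - 1))) / sigma,
    numeric(1))
}

# Given the observed normal-score correlation of a pair and the items'
# normalized Hermite coefficients, invert r_score(rho) = sum_m rho^m
# lam_i^(m) lam_j^(m) / m! for the latent correlation rho.
invert_score_correlation <- function(r_obs, lam_i, lam_j, cap = 0.999) {
  if (is.null(lam_i) || is.null(lam_j) || !is.finite(r_obs)) return(r_obs)
  m <- seq_along(lam_i)
  coefs <- lam_i * lam_j / factorial(m)
  g <- function(rho) sum(coefs * rho^m) - r_obs
  if (g(cap) < 0) return(cap)
  if (g(-cap) > 0) return(-cap)
  stats::uniroot(g, c(-cap, cap), tol = 1e-8)$root
}

#' Resample synthetic profiles from a fitted copula
#'
#' Draws latent multivariate-normal vectors with the fitted latent
#' correlation, maps each coordinate through the standard normal CDF, and
#' back-transforms through the item's right-continuous empirical quantile
#' function, so marginals and rank dependence of the source profiles are
#' preserved.
#'
#' @param model a `copula_model`.
#' @param n number of profiles to draw.
#' @param seed integer seed.
#' @return n x items matrix on the original ordinal scale.
#' @export
sample_controls <- function(model, n, seed = 1) {
  stopifnot(inherits(model, "copula_model"))
  p <- length(model$items)
  # PSD repair can leave tiny negative eigenvalues at machine precision
  R <- nearest_psd(model$R, eps = 1e-10)
  L <- chol(R + diag(1e-10, p))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  U <- stats::pnorm(matrix(stats::rnorm(n * p), n, p) %*% L)
  out <- matrix(0, n, p, dimnames = list(NULL, model$items))
  for (j in seq_len(p)) {
    cdf <- model$cdf[[j]]
    idx <- 1L + findInterval(U[, j], cdf$cumprob, left.open = TRUE)
    idx <- pmin(idx, length(cdf$levels))
    out[, j] <- cdf$levels[idx]
  }
  out
}

#' Run the emulated stratified randomized trial
#'
#' Assigns participants 1:1 to arms within each suicide-attempt stratum,
#' produces post-intervention (T1) profiles by expected-influence-scaled
#' deactivation of the target domain in the intervention arm, and synthesizes
#' control-arm T1 profiles by Gaussian-copula resampling fitted to the
#' control arm's own baseline profiles within each stratum (so strata keep
#' their distinct distributions).
#'
#' @param cohort a `synthetic_cohort`.
#' @param ei `centrality_table` of the item-level network.
#' @param config a [deactivation_config()].
#' @param seed integer seed (drives randomization and copula resampling).
#' @param catalog an `item_catalog`.
#' @return object of class `trial_state`: list with `t0`, `t1` (matrices),
#'   `arm` (factor), `stratum` (character, `"SA+"`/`"SA-"`), `age`, `sex`,
#'   `ideation_t0`.
#' @export
run_trial <- function(cohort, ei, config = deactivation_config(), seed = 1,
                      catalog = panss_catalog()) {
  stratum <- ifelse(cohort$sa == 1, "SA+", "SA-")
  arm <- stratified_randomize(stratum, seed = substream_seed(seed, "arms"))
  t0 <- cohort$items
  t1 <- matrix(NA_real_, nrow(t0), ncol(t0), dimnames = dimnames(t0))
  int_idx <- which(arm == "intervention")
  t1[int_idx, ] <- deactivate(t0[int_idx, , drop = FALSE], config, ei,
                              catalog)
  for (s in unique(stratum)) {
    ctl <- which(arm == "control" & stratum == s)
    if (!length(ctl)) next
    model <- fit_copula(t0[ctl, , drop = FALSE], min_n = 30)
    t1[ctl, ] <- sample_controls(model, length(ctl),
                                 seed = substream_seed(seed,
                                                       paste0("copula-", s)))
  }
  structure(list(t0 = t0, t1 = t1, arm = arm, stratum = stratum,
                 age = cohort$age, sex = cohort$sex,
                 ideation_t0 = cohort$ideation,
                 config = config, seed = seed),
            class = "trial_state")
}

#' @export
print.trial_state <- function(x, ...) {
  cat(sprintf(
    "emulated trial: %d participants (%s), target %s, alpha = %.2f\n",
    nrow(x$t0), paste(sprintf("%s %d", levels(x$arm), table(x$arm)),
                      collapse = " / "),
    x$config$target_domain, x$config$alpha))
  invisible(x)
}
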