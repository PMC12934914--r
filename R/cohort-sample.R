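#' Sample a synthetic PANSS cohort
#'
#' Draws latent multivariate-normal profiles from the planted partial-
#' correlation model (with SA-stratum-specific mean shifts and the SA+-only
#' planted cross-domain edge), discretizes each item through its calibrated
#' cutpoints to the 1-7 severity scale, and generates the ordinal
#' suicidal-ideation outcome (0-5) from an ordered-logit model on the mean
#' Distress item score plus an SA main effect. Each participant consumes an
#' independent, deterministically derived random substream, so cohorts of
#' different sizes drawn under the same seed share a common prefix.
#'
#' @param config a `cohort_config`.
#' @param catalog an `item_catalog`.
#' @param return_latent if `TRUE`, attach the n x 31 latent draws (before
#'   discretization, stratum shifts included) as the `latent` element.
#' @return object of class `synthetic_cohort`: list with `items` (n x 30
#'   integer matrix, levels 1-7), `ideation` (integer 0-5), `sa` (0/1 stratum
#'   indicator), `age` (years), `sex` (0/1, 1 = female), and `config_hash`.
#' @export
sample_cohort <- function(config, catalog = panss_catalog(),
                          return_latent = FALSE) {
  validate_cohort_config(config)
  validate_catalog(catalog)
  if (config$n < 10)
    stop("n = ", config$n, " is too small: at least 10 participants are ",
         "required for any downstream estimator")
  nodes <- c(catalog$codes, "SUI")
  p <- length(nodes)
  P_minus <- build_planted_network(config, catalog, "SA-")
  P_plus <- build_planted_network(config, catalog, "SA+")
  chol_of <- function(P) chol(stats::cov2cor(solve(pcor_to_precision(P))))
  R <- list(chol_of(P_minus), chol_of(P_plus))  # index by sa + 1
  shift <- c(ifelse(is.na(config$sa_shift[catalog$domain_of[catalog$codes]]),
                    0, config$sa_shift[catalog$domain_of[catalog$codes]]), 0)
  thr <- item_thresholds(config, catalog)
  ic <- config$ideation_coeffs
  dst_idx <- match(domain_items(catalog, "DST"), catalog$codes)

  n <- config$n
  items <- matrix(0L, n, 30, dimnames = list(NULL, catalog$codes))
  ideation <- integer(n)
  sa <- integer(n)
  age <- numeric(n)
  sex <- integer(n)
  latent <- if (return_latent)
    matrix(NA_real_, n, p, dimnames = list(NULL, nodes)) else NULL

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    sa_i <- as.integer(stats::runif(1) < config$sa_plus_fraction)
    z <- drop(stats::rnorm(p) %*% R[[sa_i + 1L]]) + sa_i * shift
    lev <- integer(30)
    for (j in 1:30) lev[j] <- 1L + findInterval(z[j], thr[[j]])
    eta <- ic$slope * (mean(lev[dst_idx]) - 1) + ic$sa_effect * sa_i
    ideation[i] <- sum(stats::runif(1) > stats::plogis(ic$thresholds - eta))
    ad <- if (sa_i == 1L) config$age_dist$sa_plus else config$age_dist$sa_minus
    age[i] <- round(min(65, max(18, stats::rlnorm(1, ad$meanlog, ad$sdlog))))
    pf <- if (sa_i == 1L) config$sex_dist$p_female_sa_plus else
      config$sex_dist$p_female_sa_minus
    sex[i] <- as.integer(stats::runif(1) < pf)
    items[i, ] <- lev
    sa[i] <- sa_i
    if (return_latent) latent[i, ] <- z
  }
  out <- structure(list(
    items = items, ideation = ideation, sa = sa, age = age, sex = sex,
    config_hash = cohort_config_hash(config)), class = "synthetic_cohort")
  if (return_latent) out$latent <- latent
  out
}

cohort_config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE)
  sprintf("%08x", string_hash(as.character(json)))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic PANSS cohort: n = %d (SA+ %d / SA- %d), ideation levels %s\n",
    nrow(x$items), sum(x$sa == 1), sum(x$sa == 0),
    paste(range(x$ideation), collapse = "-")))
  invisible(x)
}

cohort_columns <- function(catalog = panss_catalog())
  c(catalog$codes, "SI", "SA", "AGE", "SEX")

#' Write a cohort to CSV
#'
#' Columns are the 30 item codes in scale order followed by `SI` (ideation),
#' `SA` (stratum), `AGE`, and `SEX`. The round trip through
#' [read_cohort()] is lossless.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path output file path.
#' @param catalog an `item_catalog`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, catalog = panss_catalog()) {
  df <- data.frame(cohort$items, SI = cohort$ideation, SA = cohort$sa,
                   AGE = cohort$age, SEX = cohort$sex, check.names = FALSE)
  df <- df[, cohort_columns(catalog)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the schema (all 30 item columns plus `SI`, `SA`, `AGE`, `SEX`)
#' and the value ranges: items must be integers in 1-7 and ideation an
#' integer in 0-5; the first offending cell is named in the error.
#'
#' @param path CSV file written by [write_cohort()] (or matching its schema).
#' @param catalog an `item_catalog`.
#' @return a `synthetic_cohort` (with `config_hash = NA`).
#' @export
read_cohort <- function(path, catalog = panss_catalog()) {
  df <- utils::read.csv(path, check.names = FALSE)
  expected <- cohort_columns(catalog)
  missing <- setdiff(expected, names(df))
  if (length(missing))
    stop("cohort file is missing required columns: ",
         paste(missing, collapse = ", "))
  items <- as.matrix(df[, catalog$codes])
  check_cells <- function(M, lo, hi, what) {
    bad <- which(is.na(M) | M != round(M) | M < lo | M > hi, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      r <- bad[1, 1]; c <- bad[1, 2]
      stop(sprintf(
        "%s value %s at row %d, column %s is outside the integer range %d-%d",
        what, format(M[r, c]), r, colnames(M)[c], lo, hi))
    }
  }
  check_cells(items, 1L, 7L, "item")
  si <- as.matrix(df[, "SI", drop = FALSE])
  check_cells(si, 0L, 5L, "ideation")
  storage.mode(items) <- "integer"
  structure(list(
    items = items, ideation = as.integer(df$SI), sa = as.integer(df$SA),
    age = as.numeric(df$AGE), sex = as.integer(df$SEX),
    config_hash = NA_character_), class = "synthetic_cohort")
}
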