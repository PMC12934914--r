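#' Default full-pipeline run configuration
#'
#' Nested configuration for every pipeline stage with a single global seed
#' that is split into named substreams, so adding a stage never perturbs the
#' randomness of earlier stages.
#'
#' @param seed global integer seed.
#' @param out_dir output directory for stage artifacts.
#' @param n cohort size.
#' @param alpha deactivation dose.
#' @param target_domain intervention target (default `"DST"`).
#' @param bootstrap_B bootstrap replicates for bridge edge inference.
#' @param permanova_n_perm permutations for cluster validation.
#' @param nct_n_perm permutations for the network comparison test.
#' @param nct_level `"cluster"` (default; favorable sample-size-to-node
#'   ratio) or `"item"` for the stratified network comparison.
#' @param verbose print stage progress.
#' @return a nested list of stage configurations (class `run_config`).
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("netrx-run-"),
                               n = 313, alpha = 0.5, target_domain = "DST",
                               bootstrap_B = 500, permanova_n_perm = 9999,
                               nct_n_perm = 200,
                               nct_level = c("cluster", "item"),
                               verbose = TRUE) {
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, verbose = verbose,
    cohort = cohort_config(n = n, seed = as.integer(seed)),
    glasso = glasso_config(),
    fused = fused_config(),
    deactivation = deactivation_config(target_domain = target_domain,
                                       alpha = alpha),
    classifier = classifier_spec(seed = as.integer(seed)),
    bootstrap_B = bootstrap_B,
    permanova_n_perm = permanova_n_perm,
    nct_n_perm = nct_n_perm,
    nct_level = match.arg(nct_level)), class = "run_config")
}

# Keys accepted at the top level of a run-config file, with validators.
run_config_schema <- function() {
  num_in <- function(lo, hi) function(v) is.numeric(v) && v >= lo && v <= hi
  list(
    seed = function(v) is.numeric(v) && v == round(v),
    out_dir = is.character,
    verbose = is.logical,
    n = function(v) is.numeric(v) && v >= 10,
    alpha = num_in(0, 1),
    target_domain = is.character,
    bootstrap_B = function(v) is.numeric(v) && v >= 200,
    permanova_n_perm = function(v) is.numeric(v) && v >= 1,
    nct_n_perm = function(v) is.numeric(v) && v >= 100,
    nct_level = function(v) v %in% c("cluster", "item"),
    gamma = function(v) is.numeric(v) && v >= 0)
}

#' Validate and normalize a run configuration
#'
#' Reads a flat JSON configuration file (or a list), checks every key
#' against the schema, coerces string-encoded numbers with a warning, fills
#' defaults for everything unspecified, and reports all problems together.
#'
#' @param config path to a JSON file, or a named list (an empty file or list
#'   yields the full default configuration).
#' @return a normalized `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (nchar(trimws(txt)) == 0) list() else
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  schema <- run_config_schema()
  errors <- character(0)
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    errors <- c(errors, paste0("unknown key(s): ",
                               paste(unknown, collapse = ", ")))
  config <- config[intersect(names(config), names(schema))]
  for (k in names(config)) {
    v <- config[[k]]
    want_num <- !(k %in% c("out_dir", "verbose", "target_domain",
                           "nct_level"))
    if (want_num && is.character(v) && !is.na(suppressWarnings(
      as.numeric(v)))) {
      warning("coercing ", k, " = \"", v, "\" to numeric")
      v <- as.numeric(v)
      config[[k]] <- v
    }
    if (!isTRUE(schema[[k]](v)))
      errors <- c(errors, paste0(k, " = ", format(v),
                                 " fails its range/type check"))
  }
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  args <- config[intersect(names(config),
                           names(formals(default_run_config)))]
  rc <- do.call(default_run_config, args)
  if (!is.null(config$gamma)) rc$glasso$gamma <- config$gamma
  rc
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order — simulate, estimate, communities,
#' centrality, compare, trial, evaluate — writing each stage artifact into
#' the configured output directory together with a manifest of file hashes,
#' seeds and timestamps. Rerunning with the same configuration reproduces
#' identical artifact hashes.
#'
#' @param config a `run_config` from [default_run_config()] or
#'   [validate_config()].
#' @return list with `manifest` (data frame: stage, file, md5), `results`
#'   (in-memory stage outputs) — also serialized as `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  seed_of <- function(stage) substream_seed(config$seed, stage)
  catalog <- panss_catalog()
  artifacts <- list()
  results <- list()
  add <- function(stage, file) artifacts[[length(artifacts) + 1]] <<-
    data.frame(stage = stage, file = file, stringsAsFactors = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    say("[1/7] simulate: cohort of n = ", config$cohort$n)
    cohort <- sample_cohort(config$cohort, catalog)
    f <- file.path(config$out_dir, "cohort.csv")
    write_cohort(cohort, f, catalog)
    add(stage, f)
    results$cohort <- cohort

    stage <- "estimate"
    say("[2/7] estimate: EBIC-glasso item network")
    net <- estimate_network(cohort$items, config$glasso)
    f <- file.path(config$out_dir, "network.json")
    write_network(net, f)
    add(stage, f)
    results$network <- net

    stage <- "communities"
    say("[3/7] communities: walktrap detection + PERMANOVA validation")
    partition <- detect_communities(net, catalog = catalog)
    cm <- correlation_matrix(cohort$items, config$glasso$correlation_kind)
    perma <- permanova_clusters(cm$S, partition,
                                n_perm = config$permanova_n_perm,
                                seed = seed_of("permanova"))
    f <- file.path(config$out_dir, "partition.json")
    write_partition(partition, f)
    add(stage, f)
    f <- file.path(config$out_dir, "permanova.json")
    jsonlite::write_json(list(F = perma$F, p = perma$p,
                              n_perm = perma$n_perm),
                         f, digits = NA, auto_unbox = TRUE)
    add(stage, f)
    results$partition <- partition
    results$permanova <- perma

    stage <- "centrality"
    say("[4/7] centrality: metrics, suicide bridges, target selection")
    item_cent <- centrality(net)
    scores <- aggregate_clusters(cohort, partition, include_ideation = TRUE)
    sui_net <- suicide_network(scores, config$glasso)
    inference <- bootstrap_edge_ci(scores, B = config$bootstrap_B,
                                   config = config$glasso,
                                   seed = seed_of("bootstrap"))
    bridges <- bridge_report(sui_net, inference)
    cl_cent <- centrality(sui_net)
    targets <- select_targets(item_cent, cl_cent, bridges, catalog)
    f <- file.path(config$out_dir, "centrality.tsv")
    utils::write.table(item_cent, f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    add(stage, f)
    f <- file.path(config$out_dir, "targets.json")
    jsonlite::write_json(list(targets = targets, bridges = bridges),
                         f, digits = NA, auto_unbox = TRUE)
    add(stage, f)
    results$item_centrality <- item_cent
    results$suicide_network <- sui_net
    results$bridge_inference <- inference
    results$bridges <- bridges
    results$targets <- targets

    stage <- "compare"
    say("[5/7] compare: fused glasso + network comparison test by stratum")
    plus <- cohort$sa == 1
    groups <- list(`SA+` = cohort$items[plus, , drop = FALSE],
                   `SA-` = cohort$items[!plus, , drop = FALSE])
    fused <- fused_glasso(groups, config$fused)
    nct_data <- if (config$nct_level == "cluster") {
      sc <- aggregate_clusters(cohort, partition)
      list(`SA+` = sc[plus, , drop = FALSE],
           `SA-` = sc[!plus, , drop = FALSE])
    } else groups
    nct <- network_comparison_test(nct_data[["SA+"]], nct_data[["SA-"]],
                                   n_perm = config$nct_n_perm,
                                   seed = seed_of("nct"),
                                   config = config$glasso)
    wcc <- lapply(fused$networks, within_cluster_connectivity, partition)
    f <- file.path(config$out_dir, "stratified.json")
    jsonlite::write_json(list(
      lambda1 = fused$lambda1, lambda2 = fused$lambda2,
      nct = list(p_global_strength = nct$p_global_strength,
                 p_structure = nct$p_structure,
                 observed = as.list(nct$observed)),
      within_cluster_strength = wcc), f, digits = NA, auto_unbox = TRUE)
    add(stage, f)
    results$fused <- fused
    results$nct <- nct
    results$within_cluster <- wcc

    stage <- "trial"
    say("[6/7] trial: stratified randomization, deactivation, copula arm")
    trial <- run_trial(cohort, item_cent, config$deactivation,
                       seed = seed_of("trial"), catalog = catalog)
    f <- file.path(config$out_dir, "trial.csv")
    write_trial(trial, f)
    add(stage, f)
    results$trial <- trial

    stage <- "evaluate"
    say("[7/7] evaluate: classifier, arm comparisons, sensitivity")
    clf_spec <- config$classifier
    if (clf_spec$cv_folds > 0 && any(table(cohort$ideation) == 1)) {
      say("  (a singleton ideation class prevents stratified CV; ",
          "reporting held-out accuracy only)")
      clf_spec$cv_folds <- 0L
    }
    clf <- train_classifier(cohort$items, cohort$ideation, clf_spec)
    pred_t0 <- predict_ideation(clf, trial$t0)
    pred_t1 <- predict_ideation(clf, trial$t1)
    comparisons <- lapply(sort(unique(trial$stratum)), function(s) {
      sel <- trial$stratum == s
      compare_arms(
        pred_t1[sel & trial$arm == "intervention"],
        pred_t1[sel & trial$arm == "control"],
        pred_t0[sel & trial$arm == "intervention"],
        pred_t0[sel & trial$arm == "control"])
    })
    names(comparisons) <- sort(unique(trial$stratum))
    balance <- covariate_balance(trial)
    age_cells <- age_stratified_sensitivity(trial, pred_t0, pred_t1)
    contrast <- post_network_contrast(trial, pred_t1, partition,
                                      config = config$glasso)
    report <- list(
      classifier = list(cv_accuracy = clf$cv_accuracy,
                        test_accuracy = clf$test_accuracy,
                        hidden_layers = clf$spec$hidden_layers),
      arm_comparisons = lapply(comparisons, unclass),
      covariate_balance = balance,
      age_stratified = age_cells,
      suicide_edges = contrast$edges)
    f <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report, f, digits = NA, auto_unbox = TRUE)
    add(stage, f)
    results$classifier <- clf
    results$predictions <- list(t0 = pred_t0, t1 = pred_t1)
    results$comparisons <- comparisons
    results$balance <- balance
    results$age_stratified <- age_cells
    results$contrast <- contrast
    results
  }, error = function(e) {
    manifest <- if (length(artifacts)) do.call(rbind, artifacts) else
      data.frame(stage = character(0), file = character(0))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         "\ncompleted artifacts: ",
         paste(basename(manifest$file), collapse = ", "), call. = FALSE)
  })
  manifest <- do.call(rbind, artifacts)
  manifest$md5 <- unname(tools::md5sum(manifest$file))
  meta <- list(seed = config$seed, timestamp = format(Sys.time()),
               stages = manifest)
  jsonlite::write_json(meta, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  list(manifest = manifest, results = res)
}
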