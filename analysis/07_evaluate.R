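#!/usr/bin/env Rscript
# Stage 7 -- evaluate the emulated intervention.
#
# Trains the ideation classifier on baseline profiles, predicts ideation for
# both arms at T1, compares arms per stratum (Wilcoxon-Mann-Whitney), checks
# covariate balance, runs the age-stratified sensitivity analysis, and
# contrasts the cluster-level suicide networks before and after the trial.
# Writes results/report.json.

suppressPackageStartupMessages(library(netrx))
seed <- as.integer(Sys.getenv("NETRX_SEED", "1"))

cohort <- read_cohort("results/cohort.csv")
partition <- read_partition("results/partition.json")
net <- read_network("results/network.json")
trial <- run_trial(cohort, centrality(net),
                   deactivation_config(target_domain = "DST", alpha = 0.5),
                   seed = substream_seed(seed, "trial"))

spec <- classifier_spec(seed = substream_seed(seed, "classifier"))
if (any(table(cohort$ideation) == 1)) spec$cv_folds <- 0L
clf <- train_classifier(cohort$items, cohort$ideation, spec)
print(clf)
pred_t0 <- predict_ideation(clf, trial$t0)
pred_t1 <- predict_ideation(clf, trial$t1)

comparisons <- list()
for (s in sort(unique(trial$stratum))) {
  sel <- trial$stratum == s
  cmp <- compare_arms(pred_t1[sel & trial$arm == "intervention"],
                      pred_t1[sel & trial$arm == "control"],
                      pred_t0[sel & trial$arm == "intervention"],
                      pred_t0[sel & trial$arm == "control"])
  comparisons[[s]] <- unclass(cmp)
  cat(sprintf(
    "%s: WMW p = %.2g (%s); level-0 change %+.0f%% (intervention) vs %+.0f%% (control)\n",
    s, cmp$p, cmp$direction, 100 * cmp$level0_change_intervention,
    100 * cmp$level0_change_control))
}

balance <- covariate_balance(trial)
cat("covariate balance (max |SMD| =", round(max(abs(balance$smd)), 2), "):\n")
print(balance, row.names = FALSE, digits = 2)

age_cells <- age_stratified_sensitivity(trial, pred_t0, pred_t1)
cat("age-stratified level-0 changes:\n")
print(age_cells[, c("stratum", "age_half", "arm", "n", "level0_change")],
      row.names = FALSE, digits = 2)

contrast <- post_network_contrast(trial, pred_t1, partition)
cat("Distress-suicide edge by network:\n")
print(contrast$edges, row.names = FALSE, digits = 3)

jsonlite::write_json(list(
  classifier = list(cv_accuracy = clf$cv_accuracy,
                    test_accuracy = clf$test_accuracy),
  arm_comparisons = comparisons,
  covariate_balance = balance,
  age_stratified = age_cells,
  suicide_edges = contrast$edges),
  "results/report.json", digits = NA, auto_unbox = TRUE)
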