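#!/usr/bin/env Rscript
# Stage 6 -- run the emulated stratified randomized trial.
#
# 1:1 randomization within each suicide-attempt stratum; the intervention arm
# receives expected-influence-scaled deactivation of the Distress domain at
# dose alpha = 0.5, the control arm receives Gaussian-copula resamples of its
# own baseline profiles. Writes results/trial.csv.

suppressPackageStartupMessages(library(netrx))
seed <- as.integer(Sys.getenv("NETRX_SEED", "1"))

cohort <- read_cohort("results/cohort.csv")
net <- read_network("results/network.json")
trial <- run_trial(cohort, centrality(net),
                   deactivation_config(target_domain = "DST", alpha = 0.5),
                   seed = substream_seed(seed, "trial"))
write_trial(trial, "results/trial.csv")
print(trial)

dst <- domain_items(panss_catalog(), "DST")
for (a in levels(trial$arm)) {
  rows <- trial$arm == a
  cat(sprintf("%s arm: mean DST %.2f (T0) -> %.2f (T1)\n", a,
              mean(trial$t0[rows, dst]), mean(trial$t1[rows, dst])))
}
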