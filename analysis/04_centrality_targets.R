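#!/usr/bin/env Rscript
# Stage 4 -- centrality metrics, suicide bridges, and target selection.
#
# Computes the four centrality metrics with proportional deviations, the
# bootstrap-tested bridge edges from the suicide node, and the convergent-
# evidence target ranking. Writes results/centrality.tsv and
# results/targets.json.

suppressPackageStartupMessages(library(netrx))
seed <- as.integer(Sys.getenv("NETRX_SEED", "1"))
catalog <- panss_catalog()

cohort <- read_cohort("results/cohort.csv")
net <- read_network("results/network.json")
partition <- read_partition("results/partition.json")

item_cent <- centrality(net)
write.table(item_cent, "results/centrality.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
top <- item_cent[order(-item_cent$strength_dev), ][1:5, ]
cat("items with the largest strength deviation from the network mean:\n")
print(top[, c("node", "strength", "strength_dev", "betweenness_dev")],
      row.names = FALSE)

scores <- aggregate_clusters(cohort, partition, include_ideation = TRUE)
sui_net <- suicide_network(scores)
inference <- bootstrap_edge_ci(scores, B = 500,
                               seed = substream_seed(seed, "bootstrap"))
bridges <- bridge_report(sui_net, inference)
cat("\nbridges to the suicide node (bootstrap 95% CI, family FDR):\n")
print(bridges, row.names = FALSE, digits = 3)

targets <- select_targets(item_cent, centrality(sui_net), bridges, catalog)
cat("\nconvergent-evidence target ranking:\n")
print(targets, row.names = FALSE, digits = 3)
cat(sprintf("\nselected intervention target: %s\n", targets$domain[1]))

jsonlite::write_json(list(targets = targets, bridges = bridges),
                     "results/targets.json", digits = NA, auto_unbox = TRUE)
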