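#!/usr/bin/env Rscript
# Stage 3 -- symptom communities and cluster validation.
#
# Walktrap community detection on the estimated network, PERMANOVA validation
# of the item partition, and the cluster-level suicide network built from
# domain summary scores plus the ideation item. Writes
# results/partition.json and results/communities.json.

suppressPackageStartupMessages(library(netrx))
seed <- as.integer(Sys.getenv("NETRX_SEED", "1"))
catalog <- panss_catalog()

cohort <- read_cohort("results/cohort.csv")
net <- read_network("results/network.json")
partition <- detect_communities(net, catalog = catalog)
write_partition(partition, "results/partition.json")
print(partition)

S <- correlation_matrix(cohort$items)$S
perma <- permanova_clusters(S, partition, n_perm = 9999,
                            seed = substream_seed(seed, "permanova"))
cat(sprintf("PERMANOVA: F = %.2f, permutation p = %.2g\n", perma$F, perma$p))

scores <- aggregate_clusters(cohort, partition, include_ideation = TRUE)
sui_net <- suicide_network(scores)
write_network(sui_net, "results/suicide_network.json")
cat("suicide-network edges to SUI:\n")
print(round(sui_net$weights[, "SUI"], 3))

jsonlite::write_json(list(permanova_F = perma$F, permanova_p = perma$p,
                          modularity = partition$modularity,
                          n_communities = length(partition$labels)),
                     "results/communities.json", digits = NA,
                     auto_unbox = TRUE)
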