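# netrx

Symptom-network estimation and emulated network-based intervention trials
for ordinal clinical severity data.

## The problem

In schizophrenia spectrum disorders, suicide risk is elevated several-fold,
yet no single symptom reliably predicts it. Network psychometrics treats
the 30 clinician-rated PANSS items (each scored 1 "absent" to 7 "extreme")
as nodes of a Gaussian graphical model whose edges are regularized partial
correlations: `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)` from the
l1-penalized precision matrix `Theta`, with the penalty chosen by the
extended BIC (`EBIC = -2 loglik + E log n + 4 gamma E log p`). Adding a
suicidal-ideation item (MADRS Suicidal Thoughts, 0-5) as an extra node
exposes *bridge* edges through which psychopathology connects to
suicidality, and centrality metrics (strength, expected influence, harmonic
closeness, betweenness) rank symptoms by their leverage over the rest of
the network.

`netrx` implements that whole analysis chain for researchers who want to
*simulate* what a symptom-targeted intervention would do before running a
trial: it estimates the networks, finds symptom communities (walktrap /
exploratory graph analysis) and validates them by PERMANOVA, compares
networks across suicide-attempt strata with a fused graphical lasso and a
permutation network-comparison test, and then emulates a stratified
randomized controlled trial. In the intervention arm, items of the target
domain are moved toward the scale floor in proportion to their normalized
expected influence (`x' = x - alpha * e_j * (x - 1)`); in the control arm,
post-trial profiles are resampled from a Gaussian copula fitted to the
control arm's own baseline, so the untreated joint distribution is
preserved. A two-hidden-layer neural classifier trained on baseline
profiles predicts ideation at follow-up, and arms are compared with
Wilcoxon-Mann-Whitney tests within each stratum.

Because the clinical cohort behind this design is not public, the package
ships a calibrated synthetic-cohort generator (`sample_cohort()`) whose
planted latent network, ordinal marginals, stratum contrasts, and
Distress-to-ideation bridge reproduce the published summary structure of
PANSS severity data. Every downstream stage is therefore testable against
known ground truth.

## Worked example

```r
library(netrx)

cohort <- sample_cohort(cohort_config(n = 313, seed = 1))
net    <- estimate_network(cohort$items)
part   <- detect_communities(net, catalog = panss_catalog())
print(part)
#> community partition: 5 communities, modularity 0.779
#>   COG: P2 P4 N5 N7 G5 G10 G11 G13 G15
#>   POS: P1 P3 P5 P6 G1 G9 G12 G16
#>   NEG: N1 N2 N3 N4 N6 G7
#>   HOS: P7 G8 G14
#>   DST: G2 G3 G4 G6

scores <- aggregate_clusters(cohort, part, include_ideation = TRUE)
bridges <- bridge_report(suicide_network(scores),
                         bootstrap_edge_ci(scores, B = 500, seed = 1))
bridges[1, c("target", "weight", "lower", "upper", "p_fdr")]
#>   target    weight     lower     upper      p_fdr
#> 1    DST 0.7988941 0.7383806 0.8528889 0.01996008

trial <- run_trial(cohort, centrality(net),
                   deactivation_config(target_domain = "DST", alpha = 0.5),
                   seed = 1)
clf  <- train_classifier(cohort$items, cohort$ideation,
                         classifier_spec(cv_folds = 0, seed = 1))
pred <- predict_ideation(clf, trial$t1)
sa   <- trial$stratum == "SA+"
compare_arms(pred[sa & trial$arm == "intervention"],
             pred[sa & trial$arm == "control"])
#> Wilcoxon-Mann-Whitney: U = 768.5, p = 0.000159 (intervention lower)
```

The partition recovers the five symptom domains, the only FDR-significant
suicide bridge is the Distress domain (here with a planted bridge, so the
edge is large), and after deactivating Distress at dose `alpha = 0.5`
predicted ideation in the intervention arm is stochastically lower than in
the copula-resampled control arm.

The `analysis/` directory contains the same workflow as numbered driver
scripts (`01_simulate_cohort.R` ... `07_evaluate.R`); each reads its inputs
from `results/`, prints what it found, and writes its tables back to
`results/`. Set `NETRX_SEED` to change the seed.

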