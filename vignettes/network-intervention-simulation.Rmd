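---
title: "Symptom networks and emulated intervention trials: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom networks and emulated intervention trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`netrx` estimates regularized partial-correlation networks from ordinal
symptom ratings and uses them to emulate a symptom-targeted randomized
trial. This vignette is the package's own account of the models it fits,
the synthetic data it fits them to, the tunable parameters that matter, and
the places where the design was genuinely open and a choice had to be made.

## 1. The statistical model

### Gaussian graphical model with EBIC-selected graphical lasso

Symptom profiles are modeled as a Gaussian graphical model: edges are
partial correlations `w_ij = -theta_ij / sqrt(theta_ii theta_jj)` derived
from a sparse precision matrix estimated by the l1-penalized Gaussian
log-likelihood (graphical lasso). The solver in `src/glasso.cpp` is an ADMM
iteration whose Theta-update is an eigendecomposition and whose Z-update is
off-diagonal soft-thresholding; step size is adapted by residual balancing.
The default convergence tolerance is 1e-5 (relative and absolute, both
residuals; roughly 1e-6 per entry) with at most 500 sweeps per penalty —
tight enough that selected partial correlations sit within ~1e-4 of fully
converged solutions, while roughly halving the cost of the
resampling-heavy procedures. The solver itself is validated at a tighter
tolerance: at a vanishing penalty it matches direct covariance inversion
to better than 1e-3, which the test suite asserts.

The penalty is chosen on a log-spaced grid of 100 values from
`max |off-diagonal correlation|` down to 1% of it, by the extended BIC
`-2 loglik + E log n + 4 gamma E log p` with `gamma = 0.5` — the
conservative convention of the EBIC-glasso literature. Input correlations
are Pearson on the 1-7 integers by default (Spearman is available);
polychoric correlations are deliberately not implemented, keeping the
solver's oracle exact. Empirical correlation matrices are repaired to
positive semi-definiteness by eigenvalue clipping before the solver sees
them.

### Communities, PERMANOVA, and the suicide network

Symptom communities come from walktrap random walks (4 steps, the
exploratory-graph-analysis convention) on the absolute-weight graph;
isolated nodes become singletons. igraph's walktrap is deterministic given
the graph, so partitions are reproducible; its internal tie-breaking is
used as-is rather than reimplemented. Communities are validated by a
PERMANOVA on items-as-observations with dissimilarity `1 - |r|`: a pseudo-F
from among/within sums of squared dissimilarities, with item labels
permuted for the null and the add-one p-value convention. When all pairwise
dissimilarities are equal this statistic is exactly 1 (among- and
within-group mean squares coincide), which is what "no separation" looks
like under this definition. Domain severity scores are unweighted means of
member items — the standard convention that keeps domains with different
item counts comparable — and the cluster-level "suicide network" is an
EBIC-glasso fit to the five domain scores plus the ideation item treated as
numeric.

### Edge inference and stability

Edge uncertainty comes from a nonparametric case-resampling bootstrap that
re-runs the full correlation + EBIC-glasso pipeline per replicate:
percentile 95% intervals (widened, when necessary, to contain the
full-sample point estimate so the report is internally coherent) and
sign-crossing p-values `2 min(frac <= 0, frac >= 0)` with add-one
smoothing. `bootstrap_edge_ci()` corrects p-values by Benjamini-Hochberg
across the whole upper triangle. `bridge_report()` re-applies BH within the
family of suicide-incident edges — the family actually under evaluation
when bridges are tested. The distinction matters: add-one smoothing floors
the p-value at `2/(B+1)`, so with B = 500 replicates a whole-triangle
correction over 15 edges could never fall below 0.05 no matter how strong
the edge; the within-family correction makes bridge detection possible at
realistic replicate counts while controlling the FDR over the comparisons
actually reported.

Stability uses case-dropping bootstraps: for each drop fraction,
re-estimate the network on subsamples and correlate subsample edge weights
(or node strengths) with the full-sample values; the CS coefficient is the
largest fraction whose 5th-percentile correlation still reaches 0.7.
Networks that estimate as empty contribute correlation 0 rather than NA, a
conservative convention. Subsamples smaller than 3p are skipped with a
warning.

### Stratified comparison

SA+ and SA- networks are estimated jointly by a two-group fused graphical
lasso: group-size-weighted log-likelihoods, an l1 penalty on each
precision's off-diagonal, and a fusion penalty on their difference, solved
by ADMM whose Z-update has a closed-form fuse-then-soft-threshold step.
Penalties are selected by a joint grid search (8 sparsity values, fusion
ratios 0/0.25/0.5/1 of the sparsity penalty) minimizing the summed EBIC
with each group scored at its own sample size; grid points are solved with
warm starts, and non-converged points are skipped during selection. The
implementation covers exactly two groups — the design it exists for; more
strata would need a different fusion proximal operator.

The network comparison test permutes group labels over the pooled rows and
re-estimates both networks per permutation; statistics are the absolute
global-strength difference and the maximum absolute edge difference, with
add-one p-values. Pooled rows are put in a canonical (lexicographic) order
before permuting so the test is invariant to which group is passed first
(exact for equal group sizes).

## 2. The synthetic cohort generator

No public cohort exists for this design, so `sample_cohort()` generates
one with the structure the analyses assume, and the generator is
first-class, tested code.

**Latent planted network.** A 31-node partial-correlation matrix (30 items
plus an ideation node): five within-domain blocks, a planted
Distress-to-ideation bridge (G6-SUI = 0.30), and — in the SA+ stratum only
— a Negative-Distress cross-domain edge (N2-G2 = 0.237). The implied
unit-diagonal precision matrix must be positive definite; if a
configuration is not, a diagonal ridge is added in steps and the matrix
renormalized (the default configuration needs no ridge, so planted entries
are exact). Within-domain weights (POS 0.10, COG 0.09, HOS 0.33, DST 0.28,
NEG 0.14) were chosen so that (a) all five blocks are detectable at
n = 2000, and (b) Distress items are the most central items in the network
while the other domains sit at or below the network-average strength —
matching the reported pattern in which distress symptoms (anxiety,
depression, tension) carry the highest item-level strength and betweenness
even though the Distress cluster is not the most central cluster.

**Ordinal marginals.** Latent normals are cut by per-item thresholds
derived from right-skewed per-domain target distributions (about 60% of
item mass at levels 1-2). The Distress marginal and the SA+ latent mean
shifts (DST +0.30 SD, NEG -0.35, COG -0.20, POS +0.10) were calibrated
jointly so the median Distress domain score is about 2.5 in SA+ against
2.0 in SA-, Negative severity is lower in SA+ (1.67 vs 2.0), and
Impulsive-Hostile medians sit at the scale floor — the direction and size
of published stratum contrasts.

**Ideation.** The observed 0-5 ideation level is drawn from an ordered
logit on the mean of the four Distress items (anchored at the scale floor)
with five thresholds; level 6 has zero mass by construction, matching the
reported ceiling. The slope (3.5 per PANSS unit) and thresholds
(12.0 + 4.5k) were calibrated so that a classifier trained on items alone
can reach the reported ~0.85 accuracy — ideation must be largely
determined by the observable symptom profile for that to be possible — and
so that about 80% of SA- and 65% of SA+ participants sit at level 0, with
a thin tail up to level 5. The SA main-effect term exists in the model but
defaults to 0: the stratum difference in ideation is carried by the
Distress shift, which keeps ideation a function of observables (an
unobservable direct SA effect would act as label noise no item-based
classifier could learn).

**Randomness.** Each participant consumes an independent substream seeded
by a hash of (global seed, participant index), so cohorts of different
sizes share a common prefix and every stage of the pipeline derives its
own named substream from one global seed.

**What the generator does not emulate.** Diagnosis subtypes, medication,
demographics beyond age/sex, longitudinal drift, rater effects, and any
item-level marginal detail below the domain level. Passing tests on this
generator show that the pipeline recovers structure it was designed to
plant; they do not show that real PANSS data has that structure.

## 3. The emulated trial

Arms are assigned 1:1 within each SA stratum (odd counts favor the
intervention arm). The intervention reduces each target-domain item toward
the scale floor in proportion to its normalized expected influence:
`x' = x - alpha * e_j * (x - 1)` with
`e_j = max(0, EI_j) / max_k max(0, EI_k)`. The anchoring at the floor
keeps profiles in range; clipping negative influence at zero means a
negatively connected symptom is left alone rather than amplified;
max-normalization gives the most influential item the full dose. Default
`alpha = 0.5`, continuous (unrounded) post-treatment severities; an
integer-rounding mode exists for strict scale semantics. Whether the
original procedure anchored reductions at the floor or at zero, and
whether it re-discretized, is not determinable from the available text;
both modes are provided and the floor-anchored continuous mode is the
default.

The control arm is resampled from a Gaussian copula fitted to the control
arm's own baseline profiles within each stratum, so strata keep distinct
distributions. Marginals use mid-rank empirical CDFs mapped through the
normal quantile. The latent correlation is *not* simply the Pearson
correlation of those normal scores: mid-rank scores collapse within-tie
variation, which attenuates the score correlation below the latent
correlation for heavily tied ordinals (we measured biases up to -0.11 on
resampled rank correlations). Each item's score step function is therefore
expanded in Hermite polynomials, and each pair's latent correlation is
recovered by inverting the implied score-correlation series — after which
resampled Spearman matrices match their source to within sampling noise.
The copula refuses fewer than 50 profiles in general use; the trial
orchestrator lowers that floor to 30 because a stratified 1:1 design at
n = 313 routinely leaves the SA+ control arm just under 50.

## 4. Outcome evaluation

The ideation classifier is a small ensemble (default 3) of two-hidden-layer
(16, 8) multinomial networks with logistic activations and averaged softmax,
trained by full-batch Adam (800 epochs, step 0.02, L2 1e-4) on standardized
items. Accuracy is estimated honestly — 10-fold CV inside a stratified 70%
training portion, held-out accuracy on the remaining 30% from the
70%-trained ensemble — and the deployed predictor is then refit on the full
baseline sample, which is also how the original classifier is described.
The ensemble removes initialization variance; width, depth, and ensemble
size are configuration knobs.

Arm comparisons use the Wilcoxon-Mann-Whitney test. For large arms (the
trial itself) the tie-corrected normal approximation with continuity
correction is used. For small arms — at most 20,000 ways to split the
pooled sample — the exact permutation distribution of U is enumerated
instead: with heavily tied ordinal outcomes at n = 8 + 8 the normal
approximation can be off by more than 0.2, so an exact small-sample path
is a correctness requirement, not a refinement. Covariate balance is
reported as standardized mean differences per stratum; the age sensitivity
analysis median-splits each stratum (ties to the younger half) and reports
level-0 proportion changes per cell, flagging cells under 5 participants.
Post-trial cluster networks use the classifier's predicted ideation as the
suicide variable at follow-up, since an emulated trial observes no real
post-intervention ideation.

## 5. Problem sizes used by the tests

The test suite validates properties at sizes chosen to give comfortable
statistical margins: solver oracles at n = 100p with p = 10; community,
bridge, and support recovery at n = 2000 over 20 seeds (bootstrap B = 500);
permutation-test calibration with 100-200 replicate runs at 200
permutations each; copula fidelity at 10,000 resamples of a 10,000-person
source; stability at n = 5000 with B = 500 over drop fractions
0.25/0.5/0.7; and the full emulated trial at the study scale n = 313 over
20 seeds for each dose. The fused-lasso planted-difference check runs 10
seeds at n = 1500 per stratum. `scripts/acceptance.R` re-runs the pipeline
once at n = 313 and reports its headline numbers.

## 6. Known limitations

- Pearson correlations on 1-7 integers attenuate latent associations;
  planted partial correlations are recovered in sign and order but not in
  exact magnitude at the ordinal level.
- The fused graphical lasso supports exactly two groups.
- The convergent-evidence target score is an explicit reconstruction of a
  narrative procedure (item-centrality counts, double weight for an
  FDR-significant suicide bridge, sign bonus); it is auditable but not the
  only defensible weighting, and its item-count term favors large domains
  unless centrality genuinely concentrates in the target domain.
- Emulated trials inherit every assumption above; they generate hypotheses
  about intervention targets, not evidence of clinical efficacy.
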