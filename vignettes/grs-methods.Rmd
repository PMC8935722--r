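---
title: "Tree-based genetic risk scores: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based genetic risk scores: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsforge)
```

# The problem

A genetic risk score (GRS) compresses a genotype vector
$\mathbf{x} \in \{0,1,2\}^p$ (minor-allele counts at $p$ SNPs) into an
estimated case probability. Standard linear scores assume additive
effects; when part of the signal sits in gene–gene (epistatic) or
gene–environment interactions, a linear score on marginal codings can
miss it entirely, and expanding all interactions explicitly is infeasible
($\sum_{k\ge2}\binom{50}{k} > 10^{15}$ terms for 50 SNPs). grsforge
implements GRS learners that search for such structure themselves —
logic regression, logic bagging, probability-estimation random forests
with and without shadow-variable selection — next to an elastic-net
reference, plus the simulation and evaluation machinery needed to compare
them.

# The learners

## Genotype codings

Two codings are used throughout. The additive coding passes the
minor-allele counts through unchanged; it is the default input for the
forests and the elastic net, and lets trees express both dominant
($\{0\}$ vs $\{1,2\}$) and recessive ($\{0,1\}$ vs $\{2\}$) splits.
Logic regression requires binary inputs, so each SNP is split into a
dominant indicator $\mathrm{SNP}_D = \mathbb{1}(\mathrm{SNP}\neq 0)$ and
a recessive indicator $\mathrm{SNP}_R = \mathbb{1}(\mathrm{SNP} = 2)$, in
fixed order (snp1_D, snp1_R, snp2_D, ...). The same binary coding is
available to the elastic net (`coding = "binary_01"`), where it lets a
linear model carry distinct dominant and recessive coefficients — useful
when effects are purely recessive.

## Logic regression

A logic model is
$\mathrm{logit}\,P(Y=1\mid\mathbf{x}) = \beta_0 + \sum_m \beta_m L_m(\mathbf{x})$
where each $L_m$ is a binary tree with AND/OR in the internal nodes and
possibly negated indicators in the leaves. Models are scored by the
deviance of this logistic fit and searched over the classic move set:
alternate a leaf's literal, flip an operator, grow a node (join it with a
fresh literal under a new operator), prune an internal node to one of its
children, add a single-literal tree, delete a tree. Every candidate
respects the budgets `max_trees` (ntrees) and `max_total_leaves`
(nleaves, interpreted as the **total** leaf budget across trees).

Numerical choices worth knowing:

* The logistic coefficients are estimated by iteratively reweighted least
  squares (tolerance $10^{-8}$ on the deviance, at most 50 iterations)
  with coefficients clipped at $|\beta| \le 15$, so perfectly separating
  trees yield bounded, near-0/1 predictions instead of divergence.
* Duplicate tree columns are collapsed onto their first occurrence and
  constant columns absorbed into the intercept before fitting, avoiding
  singular designs.
* Greedy descent starts from the intercept-only model, moves to the
  best-scoring neighbor while the deviance strictly improves, and breaks
  ties by enumeration order (move type, node position, feature index,
  negation) for determinism. Greedy descent terminates at a state with no
  improving single move; on data with a clear signal this is the global
  optimum of the budgeted model space (verified against exhaustive
  enumeration in the tests), but on weak or ambiguous signals it can be a
  genuine local optimum — the reason simulated annealing exists.
* Simulated annealing proposes one neighbor per iteration, drawn
  uniformly from the same move set (by category counts, without
  materializing the neighborhood), accepts deteriorations with
  probability $\exp(-\Delta\mathrm{deviance}/T)$ under geometric cooling,
  and returns the best model visited. With `auto_tune = TRUE` (default) a
  pilot random walk records proposed deviance increments and sets the
  start temperature so a typical deterioration is accepted with
  probability $\approx 0.9$ and the end temperature so late acceptance is
  essentially zero; this replaces the manual cooling-schedule inspection
  that an interactive analysis would use. The desk-scale default is
  50,000 iterations; full-scale searches use 500,000.

Logic bagging fits an ensemble of greedy logic models on bootstrap
resamples ($N$ draws with replacement; out-of-bag data plays no role
here) and averages predicted probabilities. The greedy search is used in
the ensemble for computational reasons; aggregation supplies the variance
reduction the single greedy fit lacks. Full-scale ensembles use 500 bags;
the package default is 100.

## Probability-estimation random forests

Trees are grown on bootstrap samples; at each node `mtry` candidate SNPs
are drawn uniformly **without replacement**, both ordered cut points per
SNP are evaluated, and the split minimizing the weighted child Gini
impurity $i(t) = 2p(1-p)$ is taken (ties: lowest feature index, then
lower cut). A node is declared a leaf when it is pure, smaller than twice
`min_node_size`, or no split keeps both children at `min_node_size`.
Leaves store the **in-bag empirical class-1 fraction**: this is the
probability-estimation behavior — a stratum whose true risk is 0.8 gets
a forest estimate near 0.8, where majority-vote aggregation of
classification trees would report 1.0. The forest prediction is the
exact arithmetic mean of the tree leaf probabilities. Defaults:
`mtry = floor(sqrt(p))`, `min_node_size = max(1, floor(0.01 N))`,
2000 trees at full scale (500 is the package's desk-scale default; the
validation performance of these forests saturates well below 2000 trees).

The permutation importance of a SNP is the mean increase over trees in
out-of-bag misclassification (classifying at threshold 0.5) when the
SNP's values are permuted among that tree's OOB samples. The
misclassification loss is one of several defensible choices for the
importance; it is the classic one and only the ranking matters here.
Features a tree never splits on contribute exactly zero for that tree.

The shadow-variable (Boruta-style) selection repeats, for a fixed number
of iterations (default 100, desk-scale 50): permute each SNP column into
a shadow copy, fit a forest on originals plus shadows, and record a hit
for every SNP whose importance exceeds the **maximum** shadow importance.
Exact one-sided binomial tests against hit probability $1/2$ at the 1%
level classify SNPs as confirmed / rejected / tentative. Three
simplifications relative to the canonical iterative algorithm: the number
of iterations is fixed rather than adaptive, decided features are not
removed between iterations, and tentative features are treated as not
selected. These keep the procedure deterministic, parallel-friendly and
faithful to the level of description the method comparison relies on.
The final `rfvim` model is a probability forest on the confirmed SNPs,
or the constant training-prevalence predictor when nothing is confirmed —
which is also why its association test is conservative on null data.

## Elastic net

The reference linear score solves
$\min_{\beta_0,\beta}\; -\tfrac{1}{N}\ell(\beta_0,\beta) + \lambda R_\alpha(\beta)$,
$R_\alpha(\beta) = \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2 + \alpha\lVert\beta\rVert_1$,
by coordinate descent along a warm-started $\lambda$ path (glmnet backs
the solver; the penalty, the $\alpha$ grid
$\{0.5, 0.75, 0.9, 0.99\}$, stratified seeded folds and the selection
rule are this package's contract). $\lambda$ is the cross-validated
deviance minimizer by default; the more conservative one-standard-error
rule is implemented but non-default because it shrinks weak genetic
signals away entirely. Interaction terms are deliberately not expanded.

# The simulator

Each replicate draws per-SNP MAFs uniformly from $[0.15, 0.45]$,
genotypes as Binomial(2, MAF) (Hardy–Weinberg; the standard generative
choice when only MAFs are specified), SNPs mutually independent —
emulating an LD-pruned or clumped panel. Outcomes are Bernoulli draws
from a logistic model on dominant indicators:

* **marginal**: six SNPs with a common odds ratio (1.2 / 1.5 / 1.8),
  noise SNPs 4 / 14 / 44, $n$ = 500 / 1000 / 2000 — 27 settings;
* **gene_gene**: three SNPs at odds ratio 1.2 plus one product term
  $\mathrm{SNP}_{jD}\,\mathrm{SNP}_{kD}$ with odds ratio 1.2–2.4,
  $(j,k) \in \{(1,2), (1,4), (4,5)\}$, noise 5 / 15 / 45, $n = 2000$ —
  45 settings;
* **gxe**: marginal odds ratios 1.2 / 1.5 / 1.8, a fixed gene-gene term
  (SNPs 1 and 4, odds ratio 1.8), an exposure $E_1$ at odds ratio 1.2 per
  IQR, and a product $E_2 \cdot \mathrm{SNP}_{jD}$ with odds ratio
  1.2–2.4 per IQR, $j \in \{2, 5\}$; $(E_1, E_2)$ bivariate normal with
  means 20, variances 10 and correlation $\rho \in \{0.5, 0.9\}$; 45
  noise SNPs, $n = 2000$ — 20 settings. GRS are built from genotypes
  only, as in GxE practice.

Environmental coefficients are $\log(\mathrm{OR})$ divided by the
**theoretical** normal IQR $2\,\Phi^{-1}(0.75)\,\sigma$ (4.2658 for
$\sigma^2 = 10$), not a per-sample empirical IQR — reproducible and
replicate-independent.

The intercept is calibrated once per setting by bisection so that the
Monte-Carlo mean of $\mathrm{logit}^{-1}(\eta)$ over a large calibration
sample (default $2\times10^5$) matches the 50% target within 0.005, and
is then reused across replicates. Because every replicate redraws its
MAFs, the calibration sample draws fresh MAFs **per individual**,
marginalizing over the MAF distribution; calibrating against a single
shared MAF draw would bias the across-replicate case fraction by several
percentage points. Individual replicates still scatter around 50% — the
designs are "approximately balanced", not exactly so. Per-replicate
sub-seeds are derived deterministically from the design seed, so a design
object reproduces its datasets exactly.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, missing genotypes, genotyping error, population stratification,
covariate confounding, rare variants (MAF below 0.15), and case-control
ascertainment beyond prevalence tuning. Results on simulated data
therefore speak to the learners' ability to find the planted interaction
structure under clean sampling, not to robustness against the
correlation structure of real panels.

# Evaluation

Raw risks are clipped to $[10^{-6}, 1-10^{-6}]$ and logit-transformed
(tree-based scores do produce exact 0/1 risks), then the univariate model
$\mathrm{logit}\,P(Y=1\mid \mathrm{GRS}) = \beta_0 + \beta_1\,\mathrm{GRS}$
is fitted on independent test data and $\beta_1$ tested by a two-sided
Wald test. A constant score is flagged degenerate and assigned $p = 1$:
an intercept-only association carries no evidence, and this convention is
what makes the fully-shrunk elastic net conservative under the null. The
AUC uses midranks (half credit for ties — essential for the discrete
scores these learners produce; the marginal-scenario true model itself
has only 7 distinct risk values). Classification metrics use threshold
0.5 without prevalence adjustment. Power and type-I error are rejection
fractions across replicates, reported with binomial standard errors.
Null data for type-I estimation reuse the marginal design shell with all
genetic coefficients and the intercept set to zero. The adjusted
gene-environment model
$\beta_0 + \beta_1\mathrm{GRS} + \beta_2 E + \beta_3\,\mathrm{GRS}\cdot E + \sum_i\gamma_i C_i$
is available for covariate-adjusted interaction testing; a constant
exposure collapses it to the univariate fit, and genuinely collinear
covariates raise an error naming the offending columns.

# The experiment harness

Replicate $i$ trains; its cyclic successor tests and predecessor
validates. Hyperparameters are tuned jointly per method by averaging the
validation AUC over the **first** `tuning_reps` (default 10) iterations
and freezing the best grid point (ties to the first row) for the whole
study — fidelity to the tuning protocol over statistical efficiency. The
default grids are `mtry` $= \lfloor(0.5, 1, 2)\sqrt{p}\rfloor$ crossed
with `min.node.size` $= \lfloor(0.01, 0.05, 0.1)N\rfloor$ for forests;
all (ntrees $1..6$) × (nleaves $1..10$) pairs with nleaves ≥ ntrees for
logic models; and the $\alpha$ list for the elastic net. For real data a
repeated stratified 50/50 train/test scheme with a 75/25 tuning sub-split
(validation size floored) replaces the cyclic scheme.

`run_simulation_study()` defaults to desk-scale sizes (500 trees, 100
bags, 50 shadow iterations, greedy logic search); `paper_scale = TRUE`
restores the full-scale settings (2000 trees, 500 bags, 100 iterations,
annealing with 500,000 steps). Partial method failures are recorded per
replicate and the run continues.

# Problem sizes in the tests

The test suite and the acceptance script exercise the full pipeline at
sizes chosen for a single desktop CPU: distributional checks at
$10^4$–$10^5$ draws; parameter recovery at $n = 2000$ with 50 SNPs;
power curves across odds ratios 1.2/1.5/1.8 at $n = 1000$ with 12
replicate pairs per level; the gene-environment power computation at
$n = 2000$ with 20 pairs; and type-I calibration on 100 null pairs at
$n = 1000$ with reduced forest sizes (150–300 trees). At these sizes the
Monte-Carlo standard error of a rejection fraction is 2–5 percentage
points, which the assertions account for; full-scale replication (100
replicates per setting, 2000-tree forests, 500-bag ensembles, 500,000
annealing iterations) is a matter of configuration, not code.

# Known limitations

* Logic regression handles binary outcomes only (no quantitative or
  survival responses, no MCMC model averaging) and does not canonicalize
  equivalent Boolean expressions beyond duplicate-column collapsing; a
  recovered tree may be the complement of the planted one with a negated
  coefficient — an identical model.
* The forest does not implement regression or survival modes, nor
  alternative importance schemes (Altmann, Vita).
* The annealing temperature auto-tuner is a pragmatic replacement for
  interactive cooling-schedule tuning; extremely rugged search landscapes
  may still need manual temperatures.
* The simulator's independence assumptions above.
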