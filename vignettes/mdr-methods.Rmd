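---
title: "Multifactor dimensionality reduction: model, validation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifactor dimensionality reduction: model, validation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrkit)
```

## The method

Multifactor dimensionality reduction (MDR) looks for combinations of
categorical loci — typically SNP genotypes coded 0/1/2 by minor-allele
count — that jointly predict binary case-control status, without assuming
any inheritance model or estimating regression parameters.  For a candidate
set of k loci, the n individuals are cross-classified into at most $L^k$
genotype cells (L = number of genotype levels).  Each observed cell is
pooled into one of two classes:

* **high-risk** if its case:control ratio $n_1/n_0$ exceeds a threshold T,
* **low-risk** if below; a ratio exactly equal to T follows the tie rule
  (default high-risk, matching the common `equal = "HR"` convention).

The pooled rule classifies each individual by their cell's label, and the
combination is scored by balanced accuracy
$\mathrm{BA} = \tfrac12(\mathrm{sens} + \mathrm{spec})$.  BA rather than
raw accuracy keeps scores comparable when the design is not perfectly
balanced, and reduces to raw accuracy when it is.  An exhaustive search
evaluates all $\binom{p}{k}$ combinations per interaction order k and ranks
them by training BA, ties broken by lexicographic locus order so results
are bit-reproducible.

Assumptions worth stating: the trait is binary; predictors are categorical
with a shared declared level set; individuals are exchangeable within
status strata (no family structure, covariates or population
stratification); and the sample is a retrospective case-control draw, which
is why the prospective adjustments below exist.

## Tunable parameters

* `ratio` (threshold T) — default `NULL` = the case:control ratio of the
  data being attributed, so that a cell is high-risk when cases are
  over-represented relative to the study design; this reduces to T = 1 for
  balanced data.  A user value overrides it (must be positive).  When rows
  are excluded for missing genotypes at the evaluated loci, the automatic
  ratio uses the counts actually tabulated for that combination.
* `equal` — tie rule at the threshold, `"HR"` (default) or `"LR"`.
* `K` — highest interaction order searched.  Cost grows as
  $\binom{p}{k}$ per level; K = 2–3 is the practical regime for candidate
  panels of tens of loci.
* `cv` — number of folds, default 5; 5 or 10 is the standard choice, and 5
  keeps each held-out stratum large enough for a stable BA at typical
  candidate-gene sample sizes.
* `x` (three-way split) — how many top training models advance to the
  testing stage, default 10: large enough that the training stage is a
  screen rather than the decision, small enough that the testing stage
  is not itself an exhaustive search.  Clamped to $\binom{p}{k}$ with a
  warning.
* `proportion` — train:test:validation weights, default 2:2:1: half the
  data to screen, a testing set of equal size to select among the x
  survivors, and a fifth held back for the final, untouched estimate.
* `prev` — assumed population prevalence for the prospective adjustments;
  a probability in (0, 1) supplied by the user from external knowledge.
* `B`, `b` — permutation and bootstrap replicate counts.  The permutation
  p-value is $(1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$, so the
  smallest attainable p is $1/(B+1)$; choose B accordingly.

## Internal validation

**Cross-validation** (`mdr_cv`): folds are stratified by status (sizes
within a stratum differ by at most one), so every training set keeps the
design's case:control ratio and the automatic threshold stays meaningful.
For each fold and level, the exhaustive search on the k−1 training folds
picks a best combination, which is then scored on the held-out fold.  Per
level the package reports the combination chosen most often across folds;
its **cross-validation consistency** is that count, its **classification
accuracy** is the training BA refit on the full data (this is what makes a
single number per level possible), and its **prediction accuracy** is the
mean held-out BA over the folds that chose it — folds that chose another
model say nothing about this one, so they are not averaged in.  The final
level maximizes prediction accuracy, then consistency, then parsimony
(smaller k).

**Three-way split** (`mdr_3ws`): stratified split at the given proportions
with largest-remainder rounding; remainder ties are balanced across the two
strata so that, e.g., 100 individuals at 2:1:1 give exactly 50/25/25.  Per
level, the top-x training models are each *re-attributed* on the testing
set (cells re-pooled from testing counts) and the testing winner is scored
on the validation set, classifying with cells attributed on the pooled
training + testing data — pooling uses all non-validation information while
leaving the validation set untouched.  The final level maximizes validation
accuracy, ties to the smaller order.

In both schemes the returned final model is the winning combination
re-attributed on the **full** dataset: downstream prediction and
adjustment should use every observed individual.  The reported accuracies,
by contrast, are the scheme's own honest estimates and are not recomputed.

## Post-hoc inference

**Permutation test of the fit** (`permute_fit`): status labels are permuted
uniformly; the entire pipeline — including fresh internal fold or split
randomization, seeded per replicate from the master seed — is re-run, and
the final model's prediction (CV) or validation (3WS) accuracy forms the
null sample.  Re-randomizing the internal splits matters: the observed
statistic's sampling variability includes the split, so its null must too.
The add-one p-value convention keeps p in $(0, 1]$.

**Interaction LRT** (`permute_interaction`): the observed statistic is the
deviance drop when the MDR high/low risk factor is added to a logistic
regression already containing each locus as a categorical main effect; a
constant risk factor yields exactly 0.  The null re-permutes status and
re-derives the risk factor for the same loci.  The logistic fits use a
small ridge penalty (λ = 10⁻⁶, off the intercept) in an IRLS loop so that
separated tables — routine in small permuted samples — still return a
finite, comparable deviance; replicates where fitted probabilities hit the
0/1 boundary are counted and reported.  Because the permutation is
unconditional on the main effects while the statistic is conditional, the
test is exactly calibrated when main effects are absent and only
approximately so when they are strong; the conditional alternative would
require a different resampling scheme and is out of scope here.

**Prospective adjustment**: retrospective sampling fixes the case fraction
(often ½) by design, so in-sample accuracy does not estimate accuracy in a
population where the disease has prevalence π.  `mdr_ca_adj` computes the
fixed model's sensitivity and specificity on the data and reports
$100\,[\pi\,\mathrm{sens} + (1-\pi)\,\mathrm{spec}]$ — an algebraic
identity that equals 100·BA at π = ½ and is invariant to duplicating the
data.  `boot_error` reaches the same quantity by simulation: each of b
resamples draws n individuals that are cases with probability π (binomially
by default; `fixed_cases = TRUE` fixes the count), resampling within
strata, and averages the classification error.  The two agree as
b → ∞, which the test suite checks at b = 10,000; the bootstrap
additionally yields a Monte-Carlo standard error.

## The simulator

`simulate_mdr` emulates a retrospective case-control study: genotypes are
drawn independently per locus in Hardy–Weinberg proportions
$((1-q)^2, 2q(1-q), q^2)$ from per-locus minor-allele frequencies, disease
status is Bernoulli with probability given by a penetrance table over the
causal genotypes, and sampling is rejected/continued until exactly the
requested case and control quotas are ascertained — the same conditional
design the adjustment functions assume.  `xor_penetrance(base, effect)`
builds the classic two-locus pure-epistasis benchmark: cells where exactly
one locus is heterozygous carry `base + effect`; at q = 0.5 both
single-locus penetrance marginals are flat, so all signal is interaction.

`mdr1_spec()` fixes the package's benchmark conditions: 125 cases and 125
controls at 25 SNPs, causal pair at loci 4 and 9 with q = 0.5, noise loci
at q = 0.3, base 0.1 and effect 0.2.  These values were chosen once so
that the causal pair's population-level balanced accuracy is ≈ 0.66 — a
moderate, realistic signal where cross-validation is informative rather
than trivial — and are not tuned per analysis.  The power benchmark used in
the tests raises the effect to 0.4 at n = 400, p = 20, where 5-fold CV with
K = 3 should recover the causal pair as the final model in at least 80% of
replicates.

What the simulator deliberately omits: linkage disequilibrium between loci,
population structure, genotyping error, missingness mechanisms, covariates,
and quantitative traits.  Tests passing on this generator therefore
demonstrate correctness of the MDR machinery and its calibration under the
stated design — not robustness to confounding or LD, which real data may
impose.

## Numerical and degenerate-input choices

* Risk attribution under the automatic threshold compares
  $n_1 \cdot N_0$ with $n_0 \cdot N_1$ in integer arithmetic — exact, no
  division, so ties are detected exactly.  User thresholds compare
  $n_1 - T\,n_0$ in double precision.
* Cells with cases but no controls are high-risk; controls but no cases,
  low-risk (the ratio rule's limits).  Cells never observed during
  attribution are EMPTY and predict low-risk by default (`empty =
  "exclude"` drops those individuals instead): conservative, and keeps
  every individual scored.
* Missing genotypes exclude an individual only from combinations that
  involve the missing locus, not listwise — each combination uses all rows
  complete at its own loci.
* Balanced accuracy is undefined (error) when a scored stratum is empty;
  `predict` reports `NA` rather than failing when truth labels cover only
  one stratum.
* Accuracies live on [0, 1] internally; all user-facing tables multiply by
  100 and round to two decimals, and the summary TSV round-trips exactly at
  that precision.
* All stochastic steps (folds, splits, permutations, bootstrap, simulator)
  are driven by explicit seeds; the core fit contains no randomness at all.

## Problem sizes

The test suite's heavier checks run at sizes chosen to make their
statistical assertions meaningful while staying desk-scale: 200 fuzzed
datasets (n ≤ 60, p ≤ 6) against a naive reference implementation; 50
recovery replicates at n = 400, p = 20; 200 outer replicates of the
permutation test at n = 100, p = 5, B = 99, whose rejection rate is
checked against the exact binomial 95% interval at α = 0.05; bootstrap
convergence at b = 10,000.

## Limitations

Run time grows combinatorially in p and k and linearly in n; the package
targets candidate-gene panels (tens of loci, k ≤ 3–4), not genome-wide
scans, and performs no parallelization.  The interaction permutation test's
calibration under strong main effects is approximate (above).  No
covariate adjustment, quantitative traits, family designs, or alternative
cell-fitness measures are provided.
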