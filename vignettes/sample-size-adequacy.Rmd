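---
title: "Evaluating sample-size adequacy for two-class ML studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating sample-size adequacy for two-class ML studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsize)
```

## The problem

Power analysis determines a prospective sample size from an effect size —
usually one borrowed from earlier publications, with all the bias that
entails.  `mlsize` takes the complementary, retrospective view: given data
(a pilot set, a public dataset of the same modality, or a simulation with
plausible separations), is a *decided* sample size n adequate for a
two-class classification study?  The package answers with two ingredients:

1. two aggregate Cohen's d statistics measured on the data itself, and
2. classifier learning curves estimated by repeated balanced subsampling
   with cross-validation.

## Average versus grand effect size

Per variable j, Cohen's d is the standardized mean difference
$d_j = (\bar{x}_{1j} - \bar{x}_{2j})/S_{pooled,j}$, with the usual
two-group pooled SD (weights $n_c - 1$, denominator $n_1 + n_2 - 2$) and
sample (n−1) standard deviations throughout.  Two aggregations of the
$d_j$ behave very differently when effects point in different directions:

* the **average effect size** $\bar{d} = \frac{1}{vs}\sum_j |d_j|$ averages
  magnitudes, so opposite-signed effects add up;
* the **grand effect size** $d_g$ first averages the per-variable class
  means into grand means $\mu_{g,c}$ and the per-variable class SDs into
  grand SDs $\sigma_{g,c}$, then takes
  $d_g = |\mu_{g,1}-\mu_{g,2}|/S_{pooled,g}$ — opposite-signed mean
  differences cancel before standardization.

When every variable shares the same class means and SDs the two statistics
coincide exactly; when half the variables shift up and half shift down,
$\bar{d}$ can be near 1 while $d_g$ is near 0.  The gap is therefore a
cheap diagnostic of effect-direction heterogeneity, and the adequacy
criterion below deliberately accepts *either* statistic reaching the
threshold.

**Sign convention.**  Whether the per-variable d's should be averaged
signed or as magnitudes is genuinely open; `mlsize` averages magnitudes.
The package's rationale: with signed averaging, $\bar{d}$ would collapse
for direction-heterogeneous data exactly as $d_g$ does, the two statistics
would become near-duplicates, and the divergence pattern that motivates
computing both would be unobservable.  Per-variable signed values remain
available in every summary; classes are ordered by sorted label and the
sign of $d_j$ is first-minus-second.

**Degenerate variance.**  A constant variable makes its pooled SD zero.
The default is a typed error (`mlsize_degenerate_variance`) rather than a
silent infinity, which would corrupt $\bar{d}$; `on_zero_sd = "drop"`
removes such variables with a warning instead.  Inside the subsampling
loop, where tiny subsamples occasionally produce constant columns, the
drop behaviour is used so a single degenerate draw does not abort a run.

## The simulator

`generate_dataset()` draws two balanced classes of independent Gaussians:
class 1 of variable j is Normal(0, σ²) and class 2 is Normal(d_j·σ, σ²),
so the *population* Cohen's d of variable j equals the target d_j exactly.
Targets are uniform draws from a regime-specific range on Cohen's scale —
**good**: (0.5, 1.4); **poor**: (0.01, 0.2) — or a custom range.  σ
(`noise_sd`, default 1, arbitrary units) only sets the scale; all outputs
are scale-free.

Because the raw location–scale recipe ("mean × variance + noise") does not
pin down a distribution, the package fixes the additive Gaussian form above
as the one construction under which the stated effect-size ranges hold by
design and can be verified by parameter recovery (at n = 1000 per class the
measured $\bar{d}$ sits within ±0.05 of the mean target).

The **data-quality substitution** emulates improving a poor dataset: a
seeded random subset comprising a fraction q of the variables of a
poor-regime dataset is regenerated with good-regime separations (class 2
only is perturbed).  q is a fraction of *variables*, not samples; q = 0
reproduces the plain poor dataset bit-for-bit and q = 1 a fully good one,
with measured $\bar{d}$ and downstream accuracy increasing monotonically in
between.

What the simulator does *not* emulate: correlated features (a correlation
matrix hook exists but defaults to independence), non-Gaussian noise,
class imbalance, batch structure, or label noise.  Tests passing on
simulated data therefore show that the statistics and the protocol behave
as designed, not that any particular real modality will reach the same
accuracies.

## The evaluation protocol

`build_schedule()` doubles the total sample size from 16 (the conventional
lower edge of "small sample" studies) up to the largest even count the data
supports, appending that cap.  Per size, 100 random balanced subsamples are
drawn by default (reduced in the package's own test runs; the constant
stays 100), and per subsample the two effect sizes are recorded and every
classifier family is scored by stratified k-fold cross-validation with
k = min(10, smaller-class count) — ten stratified folds are impossible with
8 samples per class, so at n = 16 the protocol runs 8 folds and records the
reduction.  Accuracy is the pooled proportion of correct out-of-fold
predictions; fold-averaged accuracy differs negligibly under
stratification.  AUC-ROC, precision, recall and F1 on the pooled
out-of-fold scores are optional per-record extras.

Aggregation gives, per (classifier, size), the mean accuracy, its
within-size SD and a normal-approximation 95% CI
(mean ± 1.96·SD/√reps — the bands are symmetric, matching how such curves
are conventionally displayed), and per consecutive size pair the relative
accuracy change 100·|acc(n₊₁) − acc(n)|/acc(n).  The *relative* definition
is chosen because observed between-size changes span two orders of
magnitude (tens of percent at n = 16 down to hundredths of a percent at
the plateau), which absolute point differences cannot express.

### Classifier defaults

Hyperparameters are deliberately plain, recorded in every output, and
overridable:

| family | implementation | defaults |
|---|---|---|
| SVM | `e1071::svm` | linear kernel, cost 1 |
| LR | `glmnet` | ridge (α = 0), λ = 0.01 |
| DT | `rpart` | minsplit 4, minbucket 2, cp 0.01 |
| NN | `nnet` | 1 hidden layer, 8 units, decay 0.1, maxit 100 |
| NB | `e1071::naiveBayes` | Gaussian |

Notes on the less obvious choices.  Plain `glm` logistic regression is
degenerate whenever variables outnumber the training fold (p = 100 versus
14 training samples at n = 16), so the L2-penalised form is the package's
logistic family.  `rpart`'s stock `minsplit = 20` cannot make a single
split at n = 16; the lowered control lets trees participate at every
schedule size.  For the neural network, 8 hidden units saturate the
capacity these Gaussian problems need: with ~100 inputs, a wider layer
multiplies training cost roughly linearly in the weight count (a 100-unit
layer carries ~10,000 weights) while leaving accuracy unchanged, and the
protocol fits thousands of networks per run — so the package defaults to
the small layer and exposes `size` for anyone who wants a wider one.
Features are standardized per training fold (statistics fit on the
training fold only, preventing leakage) for SVM/LR/NN; trees and naive
Bayes are scale-free.  The SVM contributes its decision value rather than
a Platt-scaled probability: ranking-equivalent for AUC, and it avoids an
internal five-fold calibration that would quintuple SVM cost.

### Seeds and determinism

One master seed drives everything.  Each (size, repetition) pair gets two
deterministically derived child seeds (subsample draw; CV fold assignment
and stochastic fitting), logged in the record table, so identical seeds
give identical record tables regardless of execution order, and any single
subsample can be reproduced in isolation.

## The two criteria and remediation

**Criterion 1** — `max(d̄, d_g) ≥ 0.5`, boundary inclusive.  Either
statistic suffices: direction-heterogeneous data with a strong $\bar{d}$
but collapsed $d_g$ are still discriminable, and empirically classifiers
separate such classes well.

**Criterion 2** — the decided size's accuracy is ≥ 80% (inclusive), and,
when larger sizes also reaching 80% exist, the relative change to the next
such size is < 10% (exclusive).  The 80% level mirrors the conventional
statistical-power target; the stability clause formalises "the learning
curve has plateaued".  A size's accuracy is the *best* family's mean by
default (configurable to the median), since an adequacy question is about
the data's attainable performance, not about one algorithm.  Only the next
larger qualifying size is compared by default; `comparison = "any"`
demands stability against every larger qualifying size.

When either criterion fails, trends across the schedule (relative rise
first-to-last size, with a 5% tolerance for calling something
"increasing" — small enough to ignore plateau jitter, large enough to
catch real growth) select one of three remediations:

| accuracy rising | effect size rising | recommendation |
|---|---|---|
| yes | no | more samples *and* different features |
| no | no | revise design / acquire proper features |
| — | yes | more samples (rising d will pull accuracy up) |

The fourth cell (both rising, d still short) folds into "more samples".
Single-size curves return an explicit `insufficient_schedule` outcome
instead of guessing.

## Numerical and scale choices

* Thresholds compare with plain `>=` / `<`; the boundary semantics
  (criterion 1 and the 80% level inclusive, the 10% change exclusive) are
  exact and tested at machine precision.
* The effect-size summary of the full dataset carries a fingerprint that
  the verdict checks against the curve's, warning on mixed lineages.
* The package's acceptance runs use scaled problem sizes it considers
  representative: 20 replicate seeds at 512 samples per class for the
  good-separation bound, and sizes 16–1024 with 20 repetitions per size
  for the poor-separation ceiling; 100 variables throughout, matching the
  simulator default.

## Known limitations

* Two classes only; no multi-class or regression analogue.
* Balanced designs: subsampling always draws equal halves, and the
  simulator does not model imbalance.
* Feature independence in the simulator is optimistic — correlated
  features reduce the effective dimensionality, and real datasets with
  strong correlations may plateau at different sizes than matched-d̄
  simulations.
* The criteria judge a decided size; they do not extrapolate the learning
  curve to predict the smallest adequate size.
* Effect sizes are Cohen's d on raw variables; no bias correction
  (Hedges' g) and no treatment of categorical features.
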