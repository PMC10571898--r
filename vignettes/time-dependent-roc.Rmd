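---
title: "Time-dependent ROC analysis of a censored prognostic marker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-dependent ROC analysis of a censored prognostic marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcroc)
```

## The problem

A baseline biomarker is measured once, and the clinical question is whether
it predicts an event — here, grade >= 2 late breast fibrosis after adjuvant
radiotherapy — that accrues gradually over years of follow-up. A standard
ROC analysis dichotomizes the cohort at a fixed landmark and must discard
every patient censored before it. The cumulative/dynamic time-dependent ROC
framework keeps the survival structure instead: at a horizon $t$, cases are
patients with event time $T \le t$ and controls are patients still
event-free at $t$, giving

$$\mathrm{Se}(c,t) = P(M > c \mid T \le t), \qquad
  \mathrm{Sp}(c,t) = P(M \le c \mid T > t),$$

for a marker $M$ under the convention that higher values mean higher risk.
The motivating marker, RILA (radiation-induced CD8 T-lymphocyte apoptosis,
in percent), is protective — low values flag radiosensitive patients — so
it enters every analysis negated (`negate_marker()`), and thresholds are
reported back on the original percent scale through the orientation flag.

Both quantities follow from the joint distribution
$S(c,t) = P(M > c, T > t)$:

$$\mathrm{Se}(c,t) = \frac{P(M>c) - S(c,t)}{1 - S(t)}, \qquad
  \mathrm{Sp}(c,t) = \frac{S(t) - S(c,t)}{S(t)}.$$

## The two estimators

`km_joint_survival()` plugs in the Kaplan-Meier estimator computed within
the subset $\{M > c\}$, scaled by the empirical fraction $\hat P(M > c)$,
with $\hat S(t)$ the all-subject Kaplan-Meier. It is the simplest
consistent estimator under censoring independent of the marker, but nothing
constrains the resulting Se/Sp to be monotone in $c$ or to stay inside
$[0,1]$, and it breaks down when censoring depends on the marker. The
package deliberately returns its output *unrepaired*, with a warning, so
the failure mode stays visible; the test suite carries a frozen instance
(censoring concentrated among high-marker subjects) in which Se exceeds 1.

`nne_joint_survival()` is the nearest-neighbor estimator of the bivariate
distribution: for each subject a conditional survival
$\hat S_\lambda(t \mid M_i)$ is computed by Kaplan-Meier over the
neighborhood of subjects whose mid-rank empirical marker CDF lies within
$\lambda$ of subject $i$'s (a 0/1 kernel), and

$$\hat S_\lambda(c,t) = \frac{1}{n}\sum_i 1\{M_i > c\}\,
  \hat S_\lambda(t \mid M_i).$$

Its marginal $\hat S(t) = \hat S_\lambda(-\infty, t)$ is used in the Se/Sp
identities, which keeps the estimator internally consistent
($\mathrm{Se}(-\infty,t)=1$, $\mathrm{Sp}(+\infty,t)=1$ exactly). Mid-ranks
make tied marker values share neighborhoods symmetrically, and a subject
always belongs to its own neighborhood, so no neighborhood is empty for any
admissible span.

**Span.** The half-width $\lambda$ (fraction of subjects) defaults to
$0.25\,n^{-0.20}$, the usual rate-optimal choice for this smoother; it is
recorded in every `roc_curve` object. `minimal_span(n)` $= 1/(2n)$ shrinks
each neighborhood to tied-rank subjects only; on censoring-free data the
NNE then reproduces the classical empirical ROC and its pairwise-comparison
AUC *exactly*, which is the anchor the test suite checks to $10^{-12}$
against a direct counting oracle.

**Monotonicity repair.** Finite-sample NNE output can wiggle slightly, so
`roc_curve()` clamps NNE Se/Sp to $[0,1]$ and applies a cumulative
min/max sweep along the threshold grid. This is a post-processing step of
the curve, not of the joint estimator; KM output is never repaired, to
preserve the contrast between the estimators.

**Grid.** Thresholds are the unique observed marker values plus
$\mp\infty$ sentinels. The estimators are step functions of $c$, so
evaluating the Youden index $\mathrm{Se}+\mathrm{Sp}-1$ on this grid loses
nothing. Youden ties are broken toward the higher-specificity threshold —
the conservative choice when the clinical aim is to identify patients at
low risk. A fully degenerate curve (constant marker) returns the
specificity-maximal endpoint with Youden 0 and a warning.

## From Se/Sp to clinically legible metrics

Censored-before-$t$ patients have unknown status at $t$, so a confusion
matrix cannot simply be counted. The default **expected** mode allocates
all $n$ patients from the estimated Se/Sp and the Kaplan-Meier prevalence
$p = 1 - \hat S(t)$: $TP = np\,\mathrm{Se}$, $FN = np(1-\mathrm{Se})$,
$TN = n(1-p)\mathrm{Sp}$, $FP = n(1-p)(1-\mathrm{Sp})$. The cells are
expected (non-integer) counts, sum to $n$ exactly, and make PPV and NPV
obey the Bayes identities in $p$, Se, Sp — a property the tests check
numerically. The alternative **determinate-only** mode
(`determinate_confusion()`) counts only patients whose status at $t$ is
known; it is unbiased about whom it counts but discards the censored, and
the two modes differ exactly when censoring before $t$ is substantial.
Which convention produced the published tables this design emulates is not
stated anywhere we could check, so both are provided and the default is the
one consistent with the time-dependent estimators at every horizon.

The expected misclassification cost is the weighted mean
$C = (w_{TP}\,TP + w_{FN}\,FN + w_{FP}\,FP + w_{TN}\,TN)/n$ with default
weights $(0, 2, 1, -1)$: missing a future case costs twice a false alarm,
and correctly clearing a patient who will stay fibrosis-free is rewarded,
because those patients can receive the full irradiation dose. With these
weights $C \in [-1, 2]$ and lower is better.

## The composite marker

The three-covariate Cox model
$h_i(t) = h_0(t)\exp(\beta_1(-\mathrm{RILA}_i) + \beta_2\,\mathrm{tobacco}_i
+ \beta_3\,\mathrm{HT}_i)$ is fitted by partial likelihood
(`survival::coxph`, Efron ties by default, Breslow available), and the
composite marker is the exponentiated linear predictor
$\exp(\hat\beta^\top Z_i)$. ROC curves and AUC are invariant to the
exponentiation (any strictly increasing transform), so the choice of scale
only affects where thresholds are quoted; the exp scale puts them in the
interpretable neighborhood of 1 (a score of 1 is the all-zero covariate
profile). Wald p-values and 95% CIs accompany the hazard ratios, matching
how such models are conventionally reported. Monotone likelihood (perfect
separation) is flagged as non-convergence with the underlying diagnostic
rather than returning a divergent coefficient; constant covariates raise a
degenerate-design error. Baseline-hazard estimation is deliberately absent:
$h_0$ cancels from every quantity used downstream.

Composite analyses are complete-case in tobacco and hormonotherapy status
(exclusions are counted and messaged); RILA-alone analyses use everyone.

## The synthetic cohort generator

The cohort the workflow analyses is simulated, emulating the statistical
structure of a breast-radiotherapy late-fibrosis study whose data are
confidential:

* $n = 456$ patients; target event fraction $61/456 \approx 13.4\%$ by 50
  months.
* RILA marginal: gamma with shape 2.68 and scale 6.36, solved once so the
  median is 15 and the 99th percentile 50 — consistent with the published
  marginals (case median ~10.9, control median ~15.6, range up to ~53)
  while no distributional form is published.
* Covariate prevalences $p_{\mathrm{tobacco}} = 0.35$,
  $p_{\mathrm{HT}} = 0.80$ — plausible for an adjuvant breast-cancer
  cohort; not published, so configurable and documented as assumptions.
* True log hazard-ratios $(0.04, 0.44, 1.15)$ for (negated RILA, tobacco,
  HT).
* Weibull baseline with shape 1.3 (slightly increasing hazard — late
  fibrosis accrues over years); the scale, 286.3 months, was set once by
  `calibrate_baseline()`, a monotone bisection against the simulated event
  fraction at $n = 10^5$ with common random numbers, and then frozen.
* Censoring: ~5% early dropout uniform on $(0, 36]$ months plus
  administrative censoring uniform on $[36, 50]$ months, mimicking a
  3-year assessment schedule with scattered final visits.

Event times are drawn by closed-form inversion,
$T = \mathrm{scale}\,(-\log U / e^{\beta^\top Z})^{1/\mathrm{shape}}$, so
the proportional-hazards property holds *exactly* by construction, and the
generator is deterministic given its seed (a single seeded stream with a
fixed draw order).

What the generator does **not** emulate: visit-grid discreteness (the real
study observed fibrosis at scheduled visits; we simulate continuous times,
as the time-dependent approach itself assumes), marker-dependent censoring
(the real data are suspected of it after 36 months; the mechanism is
demonstrated separately on a constructed instance), competing risks
(death/recurrence are folded into plain censoring), and longitudinal RILA
measurements. Passing tests on simulated cohorts therefore validate the
estimators and the pipeline, not any clinical claim about real patients.

## Cross-validation

`mc_cross_validate()` repeats, 500 times by default: split at random into
training (2/3, unstratified — matching how such splits are usually done)
and validation (1/3); on the training set fit the Cox model (composite
marker) and select the Youden threshold per horizon; on the validation set
recompute the time-dependent ROC, take its AUC, read Se/Sp at the *trained*
threshold (the threshold is injected into the validation grid so the step
function is evaluated exactly), and derive the expected confusion, PPV/NPV
and cost from the validation Kaplan-Meier prevalence. Metrics are averaged
over valid splits; the reported threshold column is the mean of per-split
trained thresholds and is labelled as such. Validation splits with no
events by a horizon, and training fits that fail to converge, are skipped
and counted — not resampled, which would bias the split distribution.
Split seeds are pre-drawn from the master seed, so results are reproducible
and independent of the horizon list.

`kfold_cross_validate()` runs K disjoint folds (K = 5 by default) with the
same per-fold logic. Leave-one-out is the K = n limit, where a per-fold ROC
is impossible; out-of-fold predictions are pooled (each subject scored by
the model trained without it), per-fold Youden thresholds are averaged, and
the pooled predictions are evaluated once per horizon. That pooling is a
necessary deviation from the per-fold scheme and is flagged in the result.

## Numerical choices and degenerate inputs

* Ties between an event and a censoring time: the event is ranked first
  (the censored subject is still at risk when the tied event occurs) — the
  standard product-limit convention.
* A horizon before the first event is an error naming the horizon ("no
  cases"); marginal survival 0 at the horizon makes specificity undefined
  and is likewise an error.
* Undefined PPV (no predicted positives) is `NA` with a warning, never a
  silent 0 or 1.
* A horizon beyond the last observed time carries the Kaplan-Meier
  estimate forward from the last time and sets an `extrapolated` flag.
* Cox convergence follows the survival package's Newton-Raphson with
  step-halving; the package treats any monotone-likelihood diagnostic as
  non-convergence.

## Problem sizes used in validation

The shipped test-and-validation suite works at the study's own scale where
the property concerns that scale: parameter recovery runs 200 simulated
cohorts of $n = 456$; cross-validation sanity runs the full 500-split Monte
Carlo on $n = 456$; the null-AUC check averages 50 cohorts of $n = 2000$
with ~20% censoring; oracle-equivalence checks use hundreds of small
($n \le 50$) instances where exhaustive enumeration is feasible.

## Known limitations

* The partial-likelihood MLE carries the usual first-order small-sample
  bias away from zero at ~60 events; recovery simulations at $n = 456$
  resolve it once enough replicates accumulate. It shrinks like $1/n$ (the
  suite demonstrates the scaling) and does not affect ranking-based
  quantities materially.
* The NNE estimator's span is a bias-variance dial; the default is a
  convention, not an optimum for any particular dataset.
* Only the cumulative/dynamic ROC definition is implemented — no
  incident/dynamic variant, no IPCW estimator, and no confidence intervals
  for the time-dependent AUC.
* The expected-confusion mode inherits any bias in Se/Sp; under
  marker-dependent censoring the KM-based quantities can be frankly
  invalid, which is precisely the contrast the two-estimator design keeps
  visible.
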