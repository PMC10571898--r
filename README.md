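# tdcroc

Time-dependent ROC analysis for right-censored biomarker studies, built
around the question: how well does a baseline marker predict an event that
accrues over years of follow-up, when many patients are censored before the
evaluation horizon?

The motivating setting is late breast fibrosis (grade >= 2) after adjuvant
radiotherapy, predicted from the RILA radiosensitivity assay
(radiation-induced CD8 T-lymphocyte apoptosis, in percent; low values mean
higher risk), alone or combined with tobacco smoking and adjuvant
hormonotherapy status through a Cox model. The confidential trial data are
emulated by a calibrated Weibull proportional-hazards simulator, so the
entire pipeline is reproducible and testable end to end.

## What it computes

At a horizon *t*, cases are patients with event time *T <= t* and controls
are patients still event-free at *t* (cumulative/dynamic definition):

    Se(c,t) = P(M > c | T <= t)      Sp(c,t) = P(M <= c | T > t)

Both follow from the joint survival S(c,t) = P(M > c, T > t), estimated two
ways:

* **Kaplan-Meier estimator** — product-limit within `{M > c}` scaled by the
  empirical P(M > c). Simple, but Se/Sp are not guaranteed monotone or in
  [0, 1], and marker-dependent censoring breaks it; violations are returned
  unrepaired with a warning so the failure mode stays visible.
* **Nearest-neighbor estimator (NNE)** — kernel-weighted Kaplan-Meier over
  mid-rank marker neighborhoods of half-width `span` (default
  `0.25 * n^-0.2`), giving valid, monotone curves under censoring. With
  `minimal_span(n)` it reproduces the classical empirical ROC exactly on
  censoring-free data.

On top of the curves: trapezoidal AUC, Youden-optimal thresholds
(ties broken toward higher specificity, reported back on the original
marker scale), censoring-aware expected confusion matrices from the
Kaplan-Meier prevalence, PPV/NPV, and an expected misclassification cost
with weights (TP, FN, FP, TN) = (0, 2, 1, -1) that rewards correctly
identifying patients who will stay fibrosis-free. Monte Carlo (500 random
2/3-1/3 splits), 5-fold and leave-one-out cross-validation transfer the
fitted model and threshold from training to validation data.

## Worked example

```r
library(tdcroc)

co  <- generate_cohort(sim_config(seed = 20230922))   # n = 456 cohort
m   <- negate_marker(co$rila, label = "RILA")         # low RILA = high risk
fit <- fit_cox(co)                                    # -RILA + tobacco + HT
print(fit)
evaluate_marker(co, m, horizons = c(12, 24, 36, 50))
```

prints the fitted model

```
Cox proportional-hazards model (efron ties), n = 456, 59 events
               Coefficient      HR [95% CI] p-value
rila (negated)        0.05 1.05 [1.02-1.08]  0.0028
tobacco               0.55 1.73 [1.03-2.88]  0.0370
ht                    0.44 1.55 [0.73-3.26]  0.2500
```

(per percent of RILA lost, the fibrosis hazard rises ~5%) and the
RILA-alone performance table

```
Performance of RILA (NNE estimator, expected confusion mode)
 horizon threshold threshold_original   auc    se    sp   ppv   npv   cost
  12.000   -12.913             12.913 0.674 0.822 0.600 0.053 0.992 -0.186
  24.000   -14.374             14.374 0.642 0.741 0.546 0.107 0.966 -0.049
  36.000   -12.246             12.246 0.615 0.567 0.640 0.159 0.925 -0.158
  50.000   -13.143             13.143 0.639 0.625 0.616 0.220 0.904 -0.086
```

— at 36 months a RILA cutoff near 12% separates best (patients below it are
predicted to develop fibrosis), with AUC 0.615; prevalence is low (~13% by
50 months), so NPV is high and PPV low, and the negative cost means correct
clearances outweigh the misclassification penalties.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the simulated
cohort and write tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate and persist the cohort + manifest; Kaplan-Meier fibrosis-free survival at 12/24/36/50 months |
| `02_cox_fit.R` | Cox model table and composite score `exp(lp)` |
| `03_tdroc.R` | NNE and KM time-dependent ROC curves per marker and horizon |
| `04_performance.R` | threshold/AUC/Se/Sp/PPV/NPV/cost tables for both markers |
| `05_crossval.R` | 500-split Monte Carlo and 5-fold cross-validation |

Run them in order from the repository root after installing the package.

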