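#' Misclassification cost matrix
#'
#' Weights attached to the confusion-matrix cells. The defaults `(TP = 0,
#' FN = 2, FP = 1, TN = -1)` encode the clinical priorities of dose
#' adaptation: missing a patient who will develop fibrosis (FN) is the most
#' damaging error, a false alarm (FP) costs less, and correctly identifying
#' a patient who will stay fibrosis-free (TN) is actively rewarded, because
#' those patients can receive the full irradiation dose.
#'
#' @param w_tp,w_fn,w_fp,w_tn finite real weights.
#' @return A `cost_matrix`; non-default weights are flagged in printing.
#' @export
cost_matrix <- function(w_tp = 0, w_fn = 2, w_fp = 1, w_tn = -1) {
  w <- c(tp = w_tp, fn = w_fn, fp = w_fp, tn = w_tn)
  stopifnot(all(is.finite(w)))
  structure(list(w_tp = w_tp, w_fn = w_fn, w_fp = w_fp, w_tn = w_tn,
                 default = identical(unname(w), c(0, 2, 1, -1))),
            class = "cost_matrix")
}

#' Expected confusion matrix at a horizon
#'
#' Under right censoring the true status at t of patients censored earlier is
#' unknown, so the confusion matrix cannot be counted directly. The
#' "expected" allocation distributes all n patients using the time-dependent
#' Se/Sp estimates and the Kaplan-Meier prevalence `p = 1 - S(t)`:
#' `TP = n*p*Se`, `FN = n*p*(1-Se)`, `TN = n*(1-p)*Sp`, `FP = n*(1-p)*(1-Sp)`.
#' Cell counts are expected (non-integer) counts and sum to n by
#' construction. See [determinate_confusion()] for the alternative that
#' counts only patients whose status at t is known.
#'
#' @param se,sp time-dependent sensitivity and specificity in \[0, 1\].
#' @param survival_at_t Kaplan-Meier survival estimate at the horizon.
#' @param n cohort size.
#' @param horizon months.
#' @return A `confusion_at_time` object.
#' @export
expected_confusion <- function(se, sp, survival_at_t, n, horizon) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1,
            survival_at_t >= 0, survival_at_t <= 1, n >= 1)
  p <- 1 - survival_at_t
  structure(list(tp = n * p * se, fn = n * p * (1 - se),
                 tn = n * (1 - p) * sp, fp = n * (1 - p) * (1 - sp),
                 n = n, horizon = horizon, mode = "expected"),
            class = "confusion_at_time")
}

#' Determinate-only confusion matrix at a horizon
#'
#' Counts only patients whose status at t is known: cases are events by t,
#' controls are patients followed (event-free) beyond t; patients censored
#' before t are left out, so the cells sum to at most n.
#'
#' @param x a [cohort].
#' @param marker a [marker_series] aligned with `x`.
#' @param threshold marker cutoff: predicted positive when marker >
#'   threshold.
#' @param horizon months.
#' @return A `confusion_at_time` object with `mode = "determinate-only"`.
#' @export
determinate_confusion <- function(x, marker, threshold, horizon) {
  x <- validate_cohort(x)
  if (!inherits(marker, "marker_series")) marker <- marker_series(marker)
  stopifnot(length(marker$values) == nrow(x))
  case <- x$event == 1L & x$time <= horizon
  control <- x$time > horizon
  pos <- marker$values > threshold
  structure(list(tp = sum(case & pos), fn = sum(case & !pos),
                 tn = sum(control & !pos), fp = sum(control & pos),
                 n = nrow(x), horizon = horizon, mode = "determinate-only"),
            class = "confusion_at_time")
}

#' Kaplan-Meier survival at a horizon with 95 percent confidence interval
#'
#' Product-limit estimate with Greenwood variance and log-log confidence
#' limits (via \code{survival::survfit}). A horizon beyond the last observed
#' time returns the estimate at the last time, flagged.
#'
#' @param x a [cohort].
#' @param horizon months.
#' @return A list: `estimate`, `lower`, `upper`, `horizon`, `extrapolated`.
#' @export
km_survival <- function(x, horizon) {
  x <- validate_cohort(x)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(x), conf.type = "log-log")
  s <- summary(fit, times = horizon, extend = TRUE)
  extrapolated <- horizon > max(x$time)   # estimate carried from last time
  list(estimate = as.numeric(s$surv), lower = as.numeric(s$lower),
       upper = as.numeric(s$upper), horizon = horizon,
       extrapolated = extrapolated)
}

#' Positive and negative predictive values
#'
#' `PPV = TP / (TP + FP)` and `NPV = TN / (TN + FN)`. A zero denominator (no
#' predicted positives, or no predicted negatives) yields `NA` with a
#' warning, never a silent 0 or 1.
#'
#' @param conf a `confusion_at_time`.
#' @return A list with `ppv` and `npv`.
#' @export
ppv_npv <- function(conf) {
  stopifnot(inherits(conf, "confusion_at_time"))
  ppv <- if (conf$tp + conf$fp > 0) conf$tp / (conf$tp + conf$fp) else {
    warning("no predicted positives: PPV undefined", call. = FALSE)
    NA_real_
  }
  npv <- if (conf$tn + conf$fn > 0) conf$tn / (conf$tn + conf$fn) else {
    warning("no predicted negatives: NPV undefined", call. = FALSE)
    NA_real_
  }
  list(ppv = ppv, npv = npv)
}

#' Expected misclassification cost
#'
#' The weighted mean of the confusion-matrix cells,
#' `C = (w_tp*TP + w_fn*FN + w_fp*FP + w_tn*TN) / n`; with the default
#' weights `C = (2*FN + FP - TN) / n`, bounded in \[-1, 2\]. Lower is
#' better: a marker that labels every truly event-free patient correctly
#' approaches -1.
#'
#' @param conf a `confusion_at_time`.
#' @param weights a [cost_matrix].
#' @return The scalar cost.
#' @export
misclassification_cost <- function(conf, weights = cost_matrix()) {
  stopifnot(inherits(conf, "confusion_at_time"),
            inherits(weights, "cost_matrix"), conf$n > 0)
  (weights$w_tp * conf$tp + weights$w_fn * conf$fn +
     weights$w_fp * conf$fp + weights$w_tn * conf$tn) / conf$n
}

#' Marker performance report across horizons
#'
#' For each horizon: time-dependent ROC (NNE by default), trapezoidal AUC,
#' Youden-optimal threshold, Se/Sp at that threshold, expected confusion
#' matrix from the Kaplan-Meier prevalence, PPV/NPV, and the expected
#' misclassification cost — one report row per horizon.
#'
#' @param x a [cohort].
#' @param marker a [marker_series] aligned with `x`.
#' @param horizons evaluation times in months.
#' @param estimator `"nne"` or `"km"`.
#' @param span NNE span; default [default_span()].
#' @param weights a [cost_matrix].
#' @param mode confusion-matrix convention, `"expected"` (default) or
#'   `"determinate"`.
#' @return A `performance_report` data frame with columns `horizon`,
#'   `threshold` (marker scale), `threshold_original` (original marker
#'   scale), `auc`, `se`, `sp`, `ppv`, `npv`, `cost`.
#' @export
evaluate_marker <- function(x, marker, horizons = c(12, 24, 36, 50),
                            estimator = c("nne", "km"), span = NULL,
                            weights = cost_matrix(),
                            mode = c("expected", "determinate")) {
  estimator <- match.arg(estimator)
  mode <- match.arg(mode)
  x <- validate_cohort(x)
  if (!inherits(marker, "marker_series")) marker <- marker_series(marker)
  rows <- lapply(horizons, function(t) {
    joint <- if (estimator == "nne") {
      nne_joint_survival(marker, x, t, span = span)
    } else {
      km_joint_survival(marker, x, t)
    }
    curve <- roc_curve(joint)
    opt <- youden_threshold(curve)
    km <- km_survival(x, t)
    conf <- if (mode == "expected") {
      expected_confusion(min(max(opt$se_at, 0), 1),
                         min(max(opt$sp_at, 0), 1),
                         km$estimate, nrow(x), t)
    } else {
      determinate_confusion(x, marker, opt$threshold_marker_scale, t)
    }
    pv <- ppv_npv(conf)
    data.frame(horizon = t, threshold = opt$threshold_marker_scale,
               threshold_original = opt$threshold_original_scale,
               auc = curve$auc, se = opt$se_at, sp = opt$sp_at,
               ppv = pv$ppv, npv = pv$npv,
               cost = misclassification_cost(conf, weights))
  })
  out <- do.call(rbind, rows)
  attr(out, "marker_label") <- marker$label
  attr(out, "estimator") <- estimator
  attr(out, "span") <- span %||% default_span(nrow(x))
  attr(out, "mode") <- mode
  class(out) <- c("performance_report", "data.frame")
  out
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance of %s (%s estimator, %s confusion mode)\n",
              attr(x, "marker_label"), toupper(attr(x, "estimator")),
              attr(x, "mode")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) sprintf("%.3f", v))
  print(y, row.names = FALSE)
  invisible(x)
}
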