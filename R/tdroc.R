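# Product-limit survival at a single horizon. Ties between event and
# censoring times are resolved with the event first (the censored subject is
# still at risk when the tied event occurs).
.km_at <- function(time, event, t) {
  keep <- event == 1L & time <= t
  if (!any(keep)) return(1)
  et <- time[keep]
  ut <- sort(unique(et))
  d <- tabulate(match(et, ut), nbins = length(ut))
  st <- sort(time)
  r <- length(time) - findInterval(ut, st, left.open = TRUE)  # at risk: time >= u
  prod(1 - d / r)
}

#' Joint marker-survival estimators at a horizon
#'
#' Both estimators target `S(c, t) = P(M > c, T > t)`, from which
#' time-dependent sensitivity and specificity follow as
#' `Se(c, t) = (P(M > c) - S(c, t)) / (1 - S(t))` and
#' `Sp(c, t) = (S(t) - S(c, t)) / S(t)` (cumulative cases `T <= t`, dynamic
#' controls `T > t`).
#'
#' `km_joint_survival()` uses the product-limit estimator within the subset
#' `{M > c}` times the empirical fraction `P(M > c)`, with `S(t)` the
#' all-subject Kaplan-Meier. It is simple but does not guarantee Se and Sp to
#' be monotone or bounded in \[0, 1\], and breaks down under
#' marker-dependent censoring.
#'
#' `nne_joint_survival()` is the nearest-neighbor estimator: for each subject
#' a conditional survival `S(t | M = m)` is computed by (0/1
#' kernel-weighted) Kaplan-Meier over the neighborhood of subjects whose
#' mid-rank empirical marker CDF lies within `span` of that subject's, and
#' `S(c, t)` is the average of `1{M > c} * S(t | M)`. Its marginal
#' `S(t) = S(-Inf, t)` is used in the Se/Sp identities, which keeps the
#' estimator internally consistent and (after the monotonicity sweep in
#' [roc_curve()]) bounded in \[0, 1\].
#'
#' @param marker a [marker_series] or numeric vector aligned with `x` (higher
#'   values = higher risk).
#' @param x a [cohort].
#' @param horizon evaluation time t in months; at least one event must have
#'   occurred by `horizon`.
#' @param span nearest-neighbor half-width as a fraction of subjects, in
#'   (0, 0.5); defaults to [default_span()]. Use [minimal_span()] to make the
#'   estimator coincide with the empirical (binary) quantities on
#'   censoring-free data.
#' @return A `joint_survival` object: per-subject data, the estimator label,
#'   marginal survival `s_t`, and for the NNE the per-subject conditional
#'   survivals.
#' @export
km_joint_survival <- function(marker, x, horizon) {
  d <- .joint_inputs(marker, x, horizon)
  s_t <- .km_at(d$time, d$event, horizon)
  if (s_t <= 0) stop("marginal survival is 0 at horizon ", horizon,
                     "; specificity undefined")
  structure(list(estimator = "km", horizon = horizon, marker = d$m,
                 time = d$time, event = d$event, s_t = s_t, span = NULL,
                 orientation = d$orientation, label = d$label),
            class = "joint_survival")
}

#' @rdname km_joint_survival
#' @export
nne_joint_survival <- function(marker, x, horizon, span = NULL) {
  d <- .joint_inputs(marker, x, horizon)
  n <- length(d$m)
  span <- span %||% default_span(n)
  if (!is.finite(span) || span <= 0 || span >= 0.5) {
    stop("span must lie in (0, 0.5), got ", span)
  }
  ord <- order(d$m)
  m_s <- d$m[ord]; time_s <- d$time[ord]; event_s <- d$event[ord]
  fm <- rank(m_s, ties.method = "average") / n   # mid-rank empirical CDF
  cond <- numeric(n)
  lo <- 1L; hi <- 1L
  for (i in seq_len(n)) {
    while (fm[i] - fm[lo] >= span) lo <- lo + 1L
    if (hi < i) hi <- i
    while (hi < n && fm[hi + 1L] - fm[i] < span) hi <- hi + 1L
    idx <- lo:hi   # never empty: the subject belongs to its own neighborhood
    cond[i] <- .km_at(time_s[idx], event_s[idx], horizon)
  }
  s_t <- mean(cond)
  if (s_t <= 0) stop("marginal survival is 0 at horizon ", horizon,
                     "; specificity undefined")
  structure(list(estimator = "nne", horizon = horizon, marker = m_s,
                 time = time_s, event = event_s, s_t = s_t, span = span,
                 cond_surv = cond,
                 orientation = d$orientation, label = d$label),
            class = "joint_survival")
}

.joint_inputs <- function(marker, x, horizon) {
  x <- validate_cohort(x)
  if (!inherits(marker, "marker_series")) marker <- marker_series(marker)
  if (length(marker$values) != nrow(x)) {
    stop("marker length (", length(marker$values),
         ") does not match cohort size (", nrow(x), ")")
  }
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be positive")
  if (!any(x$event == 1L & x$time <= horizon)) {
    stop("no cases: no event observed by horizon ", horizon)
  }
  list(m = marker$values, time = x$time, event = as.integer(x$event),
       orientation = marker$orientation, label = marker$label)
}

#' Default and minimal nearest-neighbor spans
#'
#' The default half-width `0.25 * n^(-0.20)` is the usual rate-optimal
#' choice for the NNE smoothing parameter. `minimal_span(n)` returns
#' `1 / (2n)`, the largest span for which each neighborhood contains only
#' subjects with tied marker values, making the NNE reproduce the empirical
#' (unsmoothed) joint distribution on censoring-free data.
#'
#' @param n number of subjects.
#' @export
default_span <- function(n) 0.25 * n^(-0.20)

#' @rdname default_span
#' @export
minimal_span <- function(n) 1 / (2 * n)

# Evaluate S_hat(c, t) of a joint_survival at arbitrary thresholds c.
.joint_eval <- function(joint, c_vals) {
  vapply(c_vals, function(cc) {
    above <- joint$marker > cc
    if (!any(above)) return(0)
    if (joint$estimator == "nne") {
      mean(joint$cond_surv[above]) * mean(above)
    } else {
      mean(above) * .km_at(joint$time[above], joint$event[above],
                           joint$horizon)
    }
  }, numeric(1))
}

#' Time-dependent ROC curve at a horizon
#'
#' Sensitivity and specificity are evaluated on the threshold grid formed by
#' the unique observed marker values plus `-Inf`/`+Inf` sentinels (the
#' estimators are step functions of the threshold, so the grid is lossless).
#' For the NNE estimator the raw values are clamped to \[0, 1\] and made
#' monotone along the grid by a cumulative sweep (finite-sample smoothing can
#' make them wiggle); Kaplan-Meier output is returned unrepaired, with a
#' warning when it leaves \[0, 1\] or loses monotonicity — the documented
#' drawback of that estimator.
#'
#' @param joint a `joint_survival` from [km_joint_survival()] or
#'   [nne_joint_survival()].
#' @param extra_thresholds optional additional cutoffs to include in the grid
#'   (e.g. a threshold learned on a training set).
#' @return An object of class `roc_curve` with fields `horizon`,
#'   `thresholds`, `se`, `sp`, `auc`, `estimator`, `span`, `n_cases`,
#'   `n_controls_at_t`, `orientation`, `label`.
#' @export
roc_curve <- function(joint, extra_thresholds = NULL) {
  stopifnot(inherits(joint, "joint_survival"))
  grid <- sort(unique(c(-Inf, joint$marker, extra_thresholds, Inf)))
  s_c <- .joint_eval(joint, grid)
  p_above <- vapply(grid, function(cc) mean(joint$marker > cc), numeric(1))
  s_t <- joint$s_t
  se <- (p_above - s_c) / (1 - s_t)
  sp <- (s_t - s_c) / s_t
  if (joint$estimator == "nne") {
    se <- cummin(pmin(pmax(se, 0), 1))   # non-increasing in c, from Se(-Inf)=1
    sp <- cummax(pmin(pmax(sp, 0), 1))   # non-decreasing in c, to Sp(+Inf)=1
  } else {
    out_of_bounds <- any(se < -1e-12 | se > 1 + 1e-12 |
                         sp < -1e-12 | sp > 1 + 1e-12)
    non_monotone <- any(diff(se) > 1e-12) || any(diff(sp) < -1e-12)
    if (out_of_bounds || non_monotone) {
      warning("Kaplan-Meier estimator produced ",
              if (out_of_bounds) "Se/Sp outside [0, 1]" else "",
              if (out_of_bounds && non_monotone) " and " else "",
              if (non_monotone) "non-monotone Se/Sp" else "",
              " at horizon ", joint$horizon,
              " (possible marker-dependent censoring); values returned ",
              "unrepaired", call. = FALSE)
    }
  }
  curve <- structure(
    list(horizon = joint$horizon, thresholds = grid, se = se, sp = sp,
         auc = NA_real_, estimator = joint$estimator, span = joint$span,
         n_cases = sum(joint$event == 1L & joint$time <= joint$horizon),
         n_controls_at_t = sum(joint$time > joint$horizon),
         orientation = joint$orientation, label = joint$label),
    class = "roc_curve")
  curve$auc <- auc_trapezoid(curve)
  curve
}

#' Trapezoidal area under a ROC curve
#'
#' Integrates sensitivity over 1 - specificity after sorting the vertices,
#' estimating the probability that a case by time t carries a higher marker
#' value than a subject still event-free at t.
#'
#' @param curve a `roc_curve`, or a list/data frame with elements `se` and
#'   `sp`.
#' @return The area, a scalar in \[0, 1\] for valid curves.
#' @export
auc_trapezoid <- function(curve) {
  fpr <- 1 - curve$sp
  se <- curve$se
  if (length(se) < 2L) stop("need at least 2 curve points")
  o <- order(fpr, se)
  fpr <- fpr[o]; se <- se[o]
  sum(diff(fpr) * (se[-1] + se[-length(se)]) / 2)
}

#' Youden-index optimal threshold
#'
#' Maximizes `Se(c, t) + Sp(c, t) - 1` over the finite threshold grid, ties
#' broken toward the threshold with the higher specificity (the clinically
#' conservative choice when the aim is to identify low-risk patients). For a
#' degenerate curve where all thresholds tie at Youden 0 (e.g. a constant
#' marker) the specificity-maximal threshold is returned with a warning.
#'
#' @param curve a `roc_curve`.
#' @return A `threshold_result` list: `threshold_marker_scale`,
#'   `threshold_original_scale` (back-transformed when the marker was
#'   negated), `youden`, `se_at`, `sp_at`.
#' @export
youden_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fin <- is.finite(curve$thresholds)
  if (!any(fin)) stop("no finite thresholds in curve")
  j <- curve$se + curve$sp - 1
  jf <- j[fin]
  best <- max(jf)
  cand <- which(fin)[jf >= best - 1e-12]
  pick <- cand[which.max(curve$sp[cand])]   # ties -> higher specificity
  if (best <= 1e-12) {
    warning("degenerate ROC curve: Youden index is 0 everywhere; ",
            "returning the specificity-maximal threshold", call. = FALSE)
  }
  thr <- curve$thresholds[pick]
  structure(list(
    threshold_marker_scale = thr,
    threshold_original_scale = if (identical(curve$orientation, "negated"))
      -thr else thr,
    youden = j[pick], se_at = curve$se[pick], sp_at = curve$sp[pick]),
    class = "threshold_result")
}

# Se/Sp of a curve at a specific threshold already present in its grid.
.curve_at <- function(curve, threshold) {
  i <- which(curve$thresholds == threshold)
  if (!length(i)) stop("threshold ", threshold, " not in curve grid; ",
                       "pass it via extra_thresholds when building the curve")
  list(se = curve$se[i[1]], sp = curve$sp[i[1]])
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "Time-dependent ROC (%s%s) for %s at t = %g months\n",
    toupper(x$estimator),
    if (!is.null(x$span)) sprintf(", span = %.4f", x$span) else "",
    x$label, x$horizon))
  cat(sprintf("  %d cases, %d controls at t; AUC = %.3f\n",
              x$n_cases, x$n_controls_at_t, x$auc))
  invisible(x)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "Youden-optimal threshold: %.4g (original scale %.4g); Se = %.3f, Sp = %.3f, J = %.3f\n",
    x$threshold_marker_scale, x$threshold_original_scale,
    x$se_at, x$sp_at, x$youden))
  invisible(x)
}
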