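#' Cross-validation configuration
#'
#' @param scheme `"monte_carlo"` (repeated random 2/3-1/3 splits, the
#'   default), `"kfold"`, or `"loo"` (leave-one-out, run as k-fold with
#'   `k = n` and pooled out-of-fold evaluation).
#' @param n_repeats number of Monte Carlo splits (default 500).
#' @param train_fraction fraction of patients in the training set.
#' @param k number of folds for `"kfold"`.
#' @param horizons evaluation times in months.
#' @param estimator,span passed to the ROC estimators.
#' @param marker `"rila"` (negated RILA alone) or `"composite"` (Cox score
#'   from RILA, tobacco and hormonotherapy, refitted on each training set).
#' @param weights a [cost_matrix].
#' @param seed master seed; per-split streams are derived from it.
#' @return A `cv_config` list.
#' @export
cv_config <- function(scheme = c("monte_carlo", "kfold", "loo"),
                      n_repeats = 500L, train_fraction = 2 / 3, k = 5L,
                      horizons = c(12, 24, 36, 50),
                      estimator = c("nne", "km"), span = NULL,
                      marker = c("rila", "composite"),
                      weights = cost_matrix(), seed = 1L) {
  cfg <- list(scheme = match.arg(scheme), n_repeats = as.integer(n_repeats),
              train_fraction = train_fraction, k = as.integer(k),
              horizons = horizons, estimator = match.arg(estimator),
              span = span, marker = match.arg(marker), weights = weights,
              seed = as.integer(seed))
  stopifnot(cfg$n_repeats >= 1L, cfg$k >= 2L,
            cfg$train_fraction > 0, cfg$train_fraction < 1,
            length(cfg$horizons) >= 1L)
  class(cfg) <- "cv_config"
  cfg
}

# Train on `train`, evaluate on `val` at each horizon; returns a data frame
# of per-horizon rows (skipped horizons reported with reason).
.cv_split_eval <- function(train, val, config) {
  mk <- .cv_markers(train, val, config)
  if (!is.null(mk$error)) {
    return(data.frame(horizon = config$horizons, threshold = NA_real_,
                      auc = NA_real_, se = NA_real_, sp = NA_real_,
                      ppv = NA_real_, npv = NA_real_, cost = NA_real_,
                      skipped = mk$error))
  }
  rows <- lapply(config$horizons, function(t) {
    res <- tryCatch({
      joint_tr <- .cv_joint(mk$train_marker, train, t, config)
      thr <- youden_threshold(roc_curve(joint_tr))$threshold_marker_scale
      joint_va <- .cv_joint(mk$val_marker, val, t, config)
      curve_va <- roc_curve(joint_va, extra_thresholds = thr)
      at <- .curve_at(curve_va, thr)
      se <- min(max(at$se, 0), 1)
      sp <- min(max(at$sp, 0), 1)
      km <- km_survival(val, t)
      conf <- expected_confusion(se, sp, km$estimate, nrow(val), t)
      pv <- suppressWarnings(ppv_npv(conf))
      data.frame(horizon = t, threshold = thr, auc = curve_va$auc,
                 se = at$se, sp = at$sp, ppv = pv$ppv, npv = pv$npv,
                 cost = misclassification_cost(conf, config$weights),
                 skipped = NA_character_)
    }, error = function(e) {
      data.frame(horizon = t, threshold = NA_real_, auc = NA_real_,
                 se = NA_real_, sp = NA_real_, ppv = NA_real_,
                 npv = NA_real_, cost = NA_real_,
                 skipped = conditionMessage(e))
    })
    res
  })
  do.call(rbind, rows)
}

.cv_joint <- function(marker, x, t, config) {
  if (config$estimator == "nne") {
    nne_joint_survival(marker, x, t, span = config$span)
  } else {
    km_joint_survival(marker, x, t)
  }
}

.cv_markers <- function(train, val, config) {
  if (config$marker == "rila") {
    list(train_marker = negate_marker(train$rila, label = "RILA"),
         val_marker = negate_marker(val$rila, label = "RILA"))
  } else {
    fit <- tryCatch(suppressMessages(fit_cox(train)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(list(error = paste("training Cox fit failed:",
                                conditionMessage(fit))))
    }
    if (!fit$converged) return(list(error = "training Cox fit non-converged"))
    list(train_marker = composite_score(fit, train),
         val_marker = composite_score(fit, val))
  }
}

.cv_summarise <- function(per_split, config) {
  valid <- per_split[is.na(per_split$skipped), , drop = FALSE]
  metrics <- c("threshold", "auc", "se", "sp", "ppv", "npv", "cost")
  summary <- do.call(rbind, lapply(config$horizons, function(t) {
    v <- valid[valid$horizon == t, , drop = FALSE]
    row <- as.data.frame(lapply(v[metrics], mean, na.rm = TRUE))
    cbind(data.frame(horizon = t), row,
          n_valid = nrow(v),
          n_skipped = sum(per_split$horizon == t & !is.na(per_split$skipped)))
  }))
  structure(list(per_split = per_split, summary = summary, config = config),
            class = "cv_result")
}

#' Monte Carlo cross-validation of a prognostic marker
#'
#' Repeats `n_repeats` times: randomly split the cohort into a training set
#' (`ceiling(train_fraction * n)` patients) and a validation set; on the
#' training set fit the Cox model (composite marker only) and pick the
#' Youden-optimal threshold per horizon; on the validation set recompute the
#' time-dependent ROC, take the AUC, read off Se/Sp at the *trained*
#' threshold, and derive the expected confusion matrix, PPV/NPV and cost from
#' the validation Kaplan-Meier prevalence. Metrics are averaged over valid
#' splits per horizon; splits without events by a horizon (or with a failed
#' training fit) are skipped and counted, not resampled. Deterministic given
#' `config$seed`.
#'
#' @param x a [cohort]; composite analyses use its complete cases.
#' @param config a [cv_config].
#' @return A `cv_result`: `per_split` (long format, one row per split x
#'   horizon, with a `skipped` reason column), `summary` (per-horizon means
#'   over valid splits plus `n_valid`/`n_skipped`), and the `config`.
#' @export
mc_cross_validate <- function(x, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  x <- if (config$marker == "composite") complete_cases(x) else
    validate_cohort(x)
  n <- nrow(x)
  n_train <- ceiling(config$train_fraction * n)
  if (n_train >= n) stop("train fraction leaves an empty validation set")
  set.seed(config$seed)
  split_seeds <- sample.int(.Machine$integer.max, config$n_repeats)
  per_split <- do.call(rbind, lapply(seq_len(config$n_repeats), function(r) {
    set.seed(split_seeds[r])
    idx <- sample.int(n, n_train)
    stopifnot(length(intersect(idx, setdiff(seq_len(n), idx))) == 0L)
    train <- validate_cohort(as.data.frame(x)[idx, , drop = FALSE])
    val <- validate_cohort(as.data.frame(x)[-idx, , drop = FALSE])
    cbind(split = r, .cv_split_eval(train, val, config))
  }))
  .cv_summarise(per_split, config)
}

#' K-fold and leave-one-out cross-validation
#'
#' Partitions the cohort into `k` folds; each fold serves once as the
#' validation set with training on the remainder, and per-fold metrics are
#' averaged as in [mc_cross_validate()]. Leave-one-out (`k = n`, or scheme
#' `"loo"`) cannot compute a ROC curve per single-subject fold, so
#' out-of-fold predictions are pooled: each subject's marker comes from the
#' model trained without it, per-fold Youden thresholds are averaged, and
#' the pooled predictions are evaluated once per horizon.
#'
#' @param x a [cohort].
#' @param config a [cv_config]; `config$k` is forced to `n` when the scheme
#'   is `"loo"`.
#' @return A `cv_result` (for pooled mode, `per_split` holds the single
#'   pooled evaluation).
#' @export
kfold_cross_validate <- function(x, config = cv_config(scheme = "kfold")) {
  stopifnot(inherits(config, "cv_config"))
  x <- if (config$marker == "composite") complete_cases(x) else
    validate_cohort(x)
  n <- nrow(x)
  k <- if (config$scheme == "loo") n else config$k
  if (k > n) stop("k (", k, ") exceeds cohort size (", n, ")")
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(k), n))
  if (k == n) return(.loo_pooled(x, fold, config))
  per_split <- do.call(rbind, lapply(seq_len(k), function(f) {
    train <- validate_cohort(as.data.frame(x)[fold != f, , drop = FALSE])
    val <- validate_cohort(as.data.frame(x)[fold == f, , drop = FALSE])
    cbind(split = f, .cv_split_eval(train, val, config))
  }))
  .cv_summarise(per_split, config)
}

# Pooled out-of-fold evaluation for leave-one-out.
.loo_pooled <- function(x, fold, config) {
  n <- nrow(x)
  pooled <- rep(NA_real_, n)
  thr_by_horizon <- matrix(NA_real_, n, length(config$horizons))
  for (f in seq_len(n)) {
    train <- validate_cohort(as.data.frame(x)[fold != f, , drop = FALSE])
    mk <- .cv_markers(train, train, config)
    if (!is.null(mk$error)) next
    # score the held-out subject with the training model / orientation
    if (config$marker == "rila") {
      pooled[fold == f] <- -x$rila[fold == f]
    } else {
      fit <- suppressMessages(fit_cox(train))
      one <- as.data.frame(x)[fold == f, , drop = FALSE]
      z <- one[, names(fit$coefficients), drop = FALSE]
      z$rila <- -z$rila
      pooled[fold == f] <- exp(as.numeric(
        as.matrix(z) %*% fit$coefficients))
    }
    for (j in seq_along(config$horizons)) {
      t <- config$horizons[j]
      thr_by_horizon[f, j] <- tryCatch({
        joint <- .cv_joint(mk$train_marker, train, t, config)
        youden_threshold(roc_curve(joint))$threshold_marker_scale
      }, error = function(e) NA_real_)
    }
  }
  if (anyNA(pooled)) {
    stop("pooled leave-one-out predictions incomplete: ",
         sum(is.na(pooled)), " fold(s) failed to train")
  }
  pooled_marker <- marker_series(
    pooled, orientation = if (config$marker == "rila") "negated" else "raw",
    label = paste0(config$marker, " (pooled out-of-fold)"))
  rows <- lapply(seq_along(config$horizons), function(j) {
    t <- config$horizons[j]
    thr <- mean(thr_by_horizon[, j], na.rm = TRUE)
    tryCatch({
      joint <- .cv_joint(pooled_marker, x, t, config)
      curve <- roc_curve(joint, extra_thresholds = thr)
      at <- .curve_at(curve, thr)
      km <- km_survival(x, t)
      conf <- expected_confusion(min(max(at$se, 0), 1),
                                 min(max(at$sp, 0), 1),
                                 km$estimate, n, t)
      pv <- suppressWarnings(ppv_npv(conf))
      data.frame(horizon = t, threshold = thr, auc = curve$auc,
                 se = at$se, sp = at$sp, ppv = pv$ppv, npv = pv$npv,
                 cost = misclassification_cost(conf, config$weights),
                 skipped = NA_character_)
    }, error = function(e) {
      data.frame(horizon = t, threshold = NA_real_, auc = NA_real_,
                 se = NA_real_, sp = NA_real_, ppv = NA_real_,
                 npv = NA_real_, cost = NA_real_,
                 skipped = conditionMessage(e))
    })
  })
  .cv_summarise(cbind(split = 1L, do.call(rbind, rows)), config)
}

#' @export
print.cv_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("%s cross-validation of the %s marker (%s estimator)\n",
              switch(cfg$scheme, monte_carlo = sprintf(
                "Monte Carlo (%d splits, train fraction %.2f)",
                cfg$n_repeats, cfg$train_fraction),
                kfold = sprintf("%d-fold", cfg$k),
                loo = "Leave-one-out (pooled)"),
              cfg$marker, toupper(cfg$estimator)))
  y <- x$summary
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round(v, 3))
  print(y, row.names = FALSE)
  invisible(x)
}
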