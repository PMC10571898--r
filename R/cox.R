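#' Fit the proportional-hazards model for late fibrosis
#'
#' Fits `h(t) = h0(t) * exp(beta1 * (-RILA) + beta2 * tobacco + beta3 * HT)`
#' by partial-likelihood maximization (Newton-Raphson via
#' \code{survival::coxph}, Efron tie handling by default). RILA enters
#' negated so that a positive coefficient means low RILA increases the
#' hazard of fibrosis. Patients with missing covariates are excluded
#' (complete-case) with a message.
#'
#' @param x a [cohort].
#' @param covariates subset of `c("rila", "tobacco", "ht")`.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @param negate_rila negate RILA before fitting (default `TRUE`).
#' @return An object of class `cox_fit` with elements `coefficients`, `se`,
#'   `hr`, `ci_lower`, `ci_upper`, `p_values` (Wald), `loglik` (null and
#'   maximized partial log-likelihood), `converged`, `tie_method`,
#'   `covariate_labels`, `n`, `n_events`, `diagnostics`.
#' @export
fit_cox <- function(x, covariates = c("rila", "tobacco", "ht"),
                    tie_method = c("efron", "breslow"),
                    negate_rila = TRUE) {
  tie_method <- match.arg(tie_method)
  covariates <- match.arg(covariates, c("rila", "tobacco", "ht"),
                          several.ok = TRUE)
  x <- complete_cases(x, covariates)
  if (sum(x$event) < 1L) stop("no events in cohort; cannot fit")
  z <- as.data.frame(x)[, covariates, drop = FALSE]
  labels <- covariates
  if (negate_rila && "rila" %in% covariates) {
    z$rila <- -z$rila
    labels[labels == "rila"] <- "rila (negated)"
  }
  const <- vapply(z, function(v) stats::var(v) == 0, logical(1))
  if (any(const)) {
    stop("degenerate design: constant covariate(s) ",
         paste(covariates[const], collapse = ", "))
  }
  dat <- cbind(data.frame(.time = x$time, .event = x$event), z)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~", paste(covariates, collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = tie_method),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  monotone <- any(grepl("infinite|did not converge|out of bounds", warn))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  ci <- exp(cbind(beta - stats::qnorm(0.975) * se,
                  beta + stats::qnorm(0.975) * se))
  structure(list(
    coefficients = stats::setNames(as.numeric(beta), covariates),
    se = stats::setNames(as.numeric(se), covariates),
    hr = hr_from_coef(as.numeric(beta)),
    ci_lower = as.numeric(ci[, 1]), ci_upper = as.numeric(ci[, 2]),
    p_values = as.numeric(2 * stats::pnorm(-abs(beta / se))),
    loglik = fit$loglik, converged = !monotone,
    tie_method = tie_method, covariate_labels = labels,
    n = nrow(x), n_events = sum(x$event),
    diagnostics = if (length(warn)) warn else NULL),
    class = "cox_fit")
}

#' Hazard ratio from a log hazard-ratio
#'
#' @param coefficient Cox regression coefficient(s).
#' @return `exp(coefficient)`.
#' @export
hr_from_coef <- function(coefficient) {
  stopifnot(all(is.finite(coefficient)))
  exp(coefficient)
}

#' Composite risk score from a fitted Cox model
#'
#' The per-patient prognostic score
#' `exp(beta1 * (-RILA) + beta2 * tobacco + beta3 * HT)`, i.e. the
#' exponentiated linear predictor of the fitted model, used as a scalar
#' marker combining RILA with smoking and hormonotherapy status. The
#' exponentiation does not affect ROC curves or AUC (they are invariant to
#' strictly increasing transformations) but fixes the scale on which
#' thresholds are reported.
#'
#' @param fit a converged `cox_fit`.
#' @param x a [cohort] with complete covariates for the fit's covariate set.
#' @return A [marker_series] labelled `"lp"` (orientation raw: higher score =
#'   higher risk).
#' @export
composite_score <- function(fit, x) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop("Cox fit did not converge; no composite score")
  x <- validate_cohort(x)
  covs <- names(fit$coefficients)
  z <- as.data.frame(x)[, covs, drop = FALSE]
  if (anyNA(z)) {
    stop("missing covariate value(s) in row(s): ",
         paste(which(!stats::complete.cases(z)), collapse = ", "),
         "; restrict the cohort with complete_cases() first")
  }
  if ("rila" %in% covs && grepl("negated", fit$covariate_labels[
        match("rila", names(fit$coefficients))])) {
    z$rila <- -z$rila
  }
  lp <- as.numeric(as.matrix(z) %*% fit$coefficients)
  marker_series(exp(lp), orientation = "raw", label = "lp")
}

#' @export
print.cox_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Cox proportional-hazards model (%s ties), n = %d, %d events\n",
              x$tie_method, x$n, x$n_events))
  if (!x$converged) {
    cat("  WARNING: fit flagged as non-converged (possible monotone",
        "likelihood)\n")
  }
  tab <- data.frame(
    Coefficient = round(x$coefficients, digits),
    `HR [95% CI]` = sprintf("%.2f [%.2f-%.2f]", x$hr, x$ci_lower,
                            x$ci_upper),
    `p-value` = signif(x$p_values, 2),
    check.names = FALSE, row.names = x$covariate_labels)
  print(tab)
  invisible(x)
}
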