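test_that("minimal-span NNE reproduces the empirical binary ROC without censoring", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:50, 1)
    time <- sample(1:30, n, replace = TRUE) + 0.5
    m <- round(rnorm(n), 1)   # rounding forces marker ties
    co <- cohort(time = time, event = rep(1L, n), rila = runif(n, 1, 99))
    t0 <- stats::median(time) + 0.1
    if (!any(time <= t0) || !any(time > t0)) next
    curve <- roc_curve(nne_joint_survival(marker_series(m), co, t0,
                                          span = minimal_span(n)))
    case <- time <= t0
    fin <- is.finite(curve$thresholds)
    emp <- oracle_binary_se_sp(m, case, curve$thresholds[fin])
    expect_equal(curve$se[fin], emp$se, tolerance = 1e-12)
    expect_equal(curve$sp[fin], emp$sp, tolerance = 1e-12)
    expect_equal(curve$auc, oracle_binary_auc(m, case), tolerance = 1e-12)
  }
})

test_that("four-subject worked example hits the oracle vertex set", {
  # times 1,3,5,7 all events, marker 4,3,2,1, horizon 4: cases have the two
  # largest markers, so c = 2.5 separates perfectly
  co <- cohort(time = c(1, 3, 5, 7), event = rep(1L, 4),
               rila = c(10, 20, 30, 40))
  m <- marker_series(c(4, 3, 2, 1))
  for (est in c("km", "nne")) {
    joint <- if (est == "km") km_joint_survival(m, co, 4) else
      nne_joint_survival(m, co, 4, span = minimal_span(4))
    curve <- roc_curve(joint, extra_thresholds = 2.5)
    at <- curve$thresholds == 2.5
    expect_equal(curve$se[at], 1, info = est)
    expect_equal(curve$sp[at], 1, info = est)
    expect_equal(curve$auc, 1, info = est)
  }
})

test_that("a horizon before the first event is an error naming the problem", {
  co <- cohort(time = c(10, 20, 30), event = c(1, 1, 0),
               rila = c(5, 10, 15))
  expect_error(nne_joint_survival(marker_series(1:3), co, 5), "no cases")
  expect_error(km_joint_survival(marker_series(1:3), co, 5), "no cases")
  expect_error(nne_joint_survival(marker_series(1:3), co, 15, span = 0.6),
               "span")
})

test_that("sentinel thresholds anchor the curve at (1,1) and (0,0)", {
  for (est in c("km", "nne")) {
    co <- rand_censored_cohort(60, 3)
    m <- marker_series(rnorm(60))
    joint <- if (est == "km") km_joint_survival(m, co, 8) else
      nne_joint_survival(m, co, 8)
    curve <- suppressWarnings(roc_curve(joint))
    k <- length(curve$thresholds)
    expect_equal(curve$thresholds[1], -Inf)
    expect_equal(curve$thresholds[k], Inf)
    expect_equal(curve$se[1], 1, info = est)
    expect_equal(curve$sp[1], 0, info = est)
    expect_equal(curve$se[k], 0, info = est)
    expect_equal(curve$sp[k], 1, info = est)
  }
})

test_that("a perfect marker passes through (0,1); a constant marker gives AUC 0.5", {
  co <- cohort(time = 1:20 + 0.5, event = rep(1L, 20), rila = runif(20, 1, 99))
  perfect <- marker_series(-(1:20))
  curve <- roc_curve(nne_joint_survival(perfect, co, 10.9,
                                        span = minimal_span(20)))
  expect_true(any(curve$se == 1 & curve$sp == 1))
  expect_equal(curve$auc, 1)

  flat <- marker_series(rep(3, 20))
  cflat <- roc_curve(nne_joint_survival(flat, co, 10.9,
                                        span = minimal_span(20)))
  expect_equal(cflat$auc, 0.5)
  expect_warning(opt <- youden_threshold(cflat), "degenerate")
  expect_equal(opt$youden, 0)
  expect_equal(opt$sp_at, 1)
})

test_that("trapezoidal AUC matches hand-computed areas", {
  mk <- function(fpr, se) structure(list(se = se, sp = 1 - fpr),
                                    class = "roc_curve")
  expect_equal(auc_trapezoid(mk(c(0, 1), c(0, 1))), 0.5)
  expect_equal(auc_trapezoid(mk(c(0, 0, 1), c(0, 1, 1))), 1)
  expect_equal(auc_trapezoid(mk(c(0, 0.5, 1), c(0, 0.8, 1))), 0.65)
  expect_error(auc_trapezoid(mk(0, 1)), "2 curve points")
})

test_that("Youden maximizer matches an exhaustive scan and prefers higher Sp on ties", {
  curve <- structure(list(
    horizon = 12, thresholds = c(-Inf, 1, 2, 3, 4, 5, Inf),
    se = c(1, 0.9, 0.85, 0.8, 0.4, 0.2, 0),
    sp = c(0, 0.3, 0.5, 0.6, 0.9, 0.95, 1),
    orientation = "raw", estimator = "nne"), class = "roc_curve")
  j <- curve$se + curve$sp - 1
  fin <- is.finite(curve$thresholds)
  opt <- youden_threshold(curve)
  expect_equal(opt$youden, max(j[fin]))
  expect_equal(opt$threshold_marker_scale, 3)
  expect_equal(opt$youden, opt$se_at + opt$sp_at - 1)
  # tie at thresholds 2 and 4 -> pick the higher-specificity one
  tied <- curve
  tied$se <- c(1, 0.9, 0.8, 0.7, 0.4, 0.2, 0)
  tied$sp <- c(0, 0.3, 0.5, 0.3, 0.9, 0.95, 1)
  expect_equal(youden_threshold(tied)$threshold_marker_scale, 4)
})

test_that("NNE Se/Sp stay in [0,1] and monotone on random censored data", {
  for (seed in 1:40) {
    n <- sample(15:80, 1)
    co <- rand_censored_cohort(n, seed + 500)
    set.seed(seed)
    m <- marker_series(rnorm(n) + 0.02 * co$time)
    t0 <- stats::quantile(co$time, 0.6)
    if (!any(co$event == 1L & co$time <= t0)) next
    curve <- roc_curve(nne_joint_survival(m, co, t0))
    expect_true(all(curve$se >= 0 & curve$se <= 1))
    expect_true(all(curve$sp >= 0 & curve$sp <= 1))
    expect_true(all(diff(curve$se) <= 1e-12))
    expect_true(all(diff(curve$sp) >= -1e-12))
    expect_gte(curve$auc, 0)
    expect_lte(curve$auc, 1)
  }
})

test_that("marker-dependent censoring drives the KM estimator out of [0,1], with a warning", {
  inst <- km_violation_instance()
  co <- cohort(time = inst$time, event = inst$event,
               rila = seq(1, 50, length.out = length(inst$time)))
  joint <- km_joint_survival(marker_series(inst$marker), co, inst$horizon)
  expect_warning(curve <- roc_curve(joint), "outside \\[0, 1\\]")
  expect_true(any(curve$se > 1 | curve$se < 0 | curve$sp > 1 | curve$sp < 0))
})

test_that("AUC is invariant under increasing transforms and flips under negation", {
  co <- cohort(time = 1:30 + 0.25, event = rep(1L, 30),
               rila = runif(30, 1, 99))
  set.seed(8)
  m <- rnorm(30)
  t0 <- 15
  auc_of <- function(v) roc_curve(nne_joint_survival(
    marker_series(v), co, t0, span = minimal_span(30)))$auc
  base <- auc_of(m)
  expect_equal(auc_of(exp(m)), base, tolerance = 1e-12)
  expect_equal(auc_of(3 * m + 7), base, tolerance = 1e-12)
  expect_equal(auc_of(-m), 1 - base, tolerance = 1e-12)
})

test_that("case sets are nested across horizons on censoring-free data", {
  set.seed(123)
  co <- cohort(time = sample(1:50, 25) + 0.5, event = rep(1L, 25),
               rila = runif(25, 1, 99))
  m <- marker_series(rnorm(25))
  c1 <- roc_curve(nne_joint_survival(m, co, 10, span = minimal_span(25)))
  c2 <- roc_curve(nne_joint_survival(m, co, 30, span = minimal_span(25)))
  expect_lte(c1$n_cases, c2$n_cases)
  expect_equal(c1$n_cases, sum(co$time <= 10))
  expect_equal(c2$n_cases, sum(co$time <= 30))
})
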