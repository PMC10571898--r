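test_that("expected confusion allocates all n by prevalence, Se and Sp", {
  conf <- expected_confusion(se = 0.6, sp = 0.7, survival_at_t = 0.8,
                             n = 100, horizon = 24)
  expect_equal(conf$tp, 12)
  expect_equal(conf$fn, 8)
  expect_equal(conf$tn, 56)
  expect_equal(conf$fp, 24)
  expect_equal(conf$tp + conf$fn + conf$tn + conf$fp, 100)
  # perfect classification leaves no errors; zero prevalence, no cases
  c1 <- expected_confusion(1, 1, 0.8, 50, 12)
  expect_equal(c1$fn + c1$fp, 0)
  c0 <- expected_confusion(0.9, 0.5, 1, 50, 12)
  expect_equal(c0$tp + c0$fn, 0)
})

test_that("confusion marginals equal prevalence exactly (property)", {
  set.seed(31)
  for (i in 1:200) {
    se <- runif(1); sp <- runif(1); s <- runif(1); n <- sample(10:500, 1)
    conf <- expected_confusion(se, sp, s, n, 12)
    expect_equal((conf$tp + conf$fn) / n, 1 - s, tolerance = 1e-12)
    expect_equal((conf$tn + conf$fp) / n, s, tolerance = 1e-12)
  }
})

test_that("km_survival matches hand product-limit computations", {
  # no censoring: 3 of 10 events by t gives 0.7
  co <- cohort(time = c(1, 2, 3, 11:17), event = rep(1L, 10),
               rila = runif(10, 1, 99))
  expect_equal(km_survival(co, 10)$estimate, 0.7)
  # times (1+, 2, 3+, 4), events at 2 and 4: S(4) = (1 - 1/3)(1 - 1/1) = 0
  co2 <- cohort(time = c(1, 2, 3, 4), event = c(0, 1, 0, 1),
                rila = runif(4, 1, 99))
  expect_equal(km_survival(co2, 4)$estimate, 0)
  # all censored: survival stays 1, CI degenerate
  co3 <- cohort(time = c(5, 6, 7), event = c(0, 0, 0), rila = c(1, 2, 3))
  expect_equal(km_survival(co3, 6)$estimate, 1)
  # horizon beyond follow-up is flagged
  expect_true(km_survival(co2, 99)$extrapolated)
  expect_false(km_survival(co2, 3)$extrapolated)
})

test_that("km_survival reproduces survfit's Greenwood log-log interval", {
  co <- rand_censored_cohort(80, 17)
  km <- km_survival(co, 8)
  expect_true(km$lower < km$estimate && km$estimate < km$upper)
})

test_that("PPV and NPV follow the counting formulas and flag empty denominators", {
  conf <- expected_confusion(0.6, 0.7, 0.8, 100, 24)
  pv <- ppv_npv(conf)
  expect_equal(pv$ppv, 12 / 36, tolerance = 1e-12)
  expect_equal(pv$npv, 56 / 64, tolerance = 1e-12)
  all_right <- expected_confusion(1, 1, 0.7, 40, 24)
  expect_equal(unlist(ppv_npv(all_right)), c(ppv = 1, npv = 1))
  none_pos <- expected_confusion(0, 1, 0.7, 40, 24)
  expect_warning(pv2 <- ppv_npv(none_pos), "PPV undefined")
  expect_true(is.na(pv2$ppv))
})

test_that("PPV obeys the Bayes identity when fed expected counts (property)", {
  set.seed(77)
  for (i in 1:200) {
    se <- runif(1, 0.05, 0.95); sp <- runif(1, 0.05, 0.95)
    s <- runif(1, 0.05, 0.95); p <- 1 - s
    conf <- expected_confusion(se, sp, s, sample(5:500, 1), 36)
    pv <- ppv_npv(conf)
    expect_equal(pv$ppv, se * p / (se * p + (1 - sp) * (1 - p)),
                 tolerance = 1e-12)
    expect_equal(pv$npv, sp * s / (sp * s + (1 - se) * p),
                 tolerance = 1e-12)
  }
})

test_that("misclassification cost evaluates the weighted mean and stays bounded", {
  w <- cost_matrix()
  n <- 57
  all_tn <- structure(list(tp = 0, fn = 0, fp = 0, tn = n, n = n,
                           horizon = 12, mode = "expected"),
                      class = "confusion_at_time")
  expect_equal(misclassification_cost(all_tn, w), -1)
  all_fn <- structure(list(tp = 0, fn = n, fp = 0, tn = 0, n = n,
                           horizon = 12, mode = "expected"),
                      class = "confusion_at_time")
  expect_equal(misclassification_cost(all_fn, w), 2)
  conf <- expected_confusion(0.6, 0.7, 0.8, 100, 24)
  expect_equal(misclassification_cost(conf, w), -0.16)
  # bounds and monotonicity over random confusion tables
  set.seed(13)
  for (i in 1:100) {
    cells <- as.list(stats::rmultinom(1, 200, runif(4, 0.05, 1))[, 1])
    names(cells) <- c("tp", "fn", "fp", "tn")
    conf <- structure(c(cells, n = 200, horizon = 12, mode = "expected"),
                      class = "confusion_at_time")
    cc <- misclassification_cost(conf, w)
    expect_gte(cc, -1)
    expect_lte(cc, 2)
    # moving one patient from TN to FN raises the cost
    if (cells$tn >= 1) {
      worse <- conf; worse$tn <- conf$tn - 1; worse$fn <- conf$fn + 1
      expect_gt(misclassification_cost(worse, w), cc)
    }
  }
})

test_that("non-default cost weights are honoured and flagged", {
  w <- cost_matrix(w_fn = 5)
  expect_false(w$default)
  expect_true(cost_matrix()$default)
  all_fn <- structure(list(tp = 0, fn = 10, fp = 0, tn = 0, n = 10,
                           horizon = 12, mode = "expected"),
                      class = "confusion_at_time")
  expect_equal(misclassification_cost(all_fn, w), 5)
})

test_that("determinate-only confusion counts only known statuses", {
  co <- cohort(time = c(5, 8, 20, 30, 2), event = c(1, 0, 0, 0, 1),
               rila = runif(5, 1, 99))
  m <- marker_series(c(10, 9, 1, 2, 8))
  conf <- determinate_confusion(co, m, threshold = 5, horizon = 10)
  # cases: P1, P5 (events by 10); controls: P3, P4; P2 censored at 8: unknown
  expect_equal(conf$mode, "determinate-only")
  expect_equal(conf$tp, 2)
  expect_equal(conf$fn, 0)
  expect_equal(conf$tn, 2)
  expect_equal(conf$fp, 0)
  expect_lte(conf$tp + conf$fn + conf$fp + conf$tn, conf$n)
})

test_that("evaluate_marker assembles a coherent per-horizon report", {
  # perfect marker without censoring: all metrics ideal, cost = -(1 - p)
  co <- cohort(time = 1:20 + 0.5, event = rep(1L, 20),
               rila = runif(20, 1, 99))
  rep1 <- evaluate_marker(co, marker_series(-(1:20)), horizons = c(10.9),
                          span = minimal_span(20))
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$se, 1)
  expect_equal(rep1$sp, 1)
  expect_equal(rep1$ppv, 1)
  expect_equal(rep1$npv, 1)
  p <- mean(co$time <= 10.9)
  expect_equal(rep1$cost, -(1 - p))

  # default synthetic cohort: four rows, low prevalence forces NPV >> PPV
  co2 <- generate_cohort(sim_config(seed = 14))
  m2 <- negate_marker(co2$rila, label = "RILA")
  rep2 <- evaluate_marker(co2, m2, horizons = c(12, 24, 36, 50))
  expect_equal(nrow(rep2), 4)
  expect_true(all(rep2$npv > rep2$ppv))
  expect_true(all(rep2$auc > 0.5))
  expect_equal(rep2$threshold_original, -rep2$threshold)
})
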