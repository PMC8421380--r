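test_that("AUC matches pair counting on worked examples and edge cases", {
  lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  sc <- c(3, 5, 1, 2, 4)
  r <- roc_auc(sc, lab)
  expect_equal(r$auc, 5 / 6, tolerance = 1e-12)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  # perfectly separated
  expect_equal(roc_auc(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  # ROC curve is monotone in construction order
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  # single-class input is degenerate
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "degenerate")
  # NA scores (unevaluable recordings) are dropped, not imputed
  r2 <- roc_auc(c(sc, NA), c(lab, TRUE))
  expect_equal(r2$auc, 5 / 6, tolerance = 1e-12)
  expect_equal(r2$n_dropped, 1L)
})

test_that("labels independent of scores give a null AUC near one half", {
  set.seed(51)
  sc <- rnorm(10000)
  lab <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  expect_lt(abs(roc_auc(sc, lab)$auc - 0.5), 0.02)
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(52)
  sc <- rnorm(300)
  lab <- runif(300) < plogis(sc)
  a0 <- roc_auc(sc, lab)$auc
  expect_equal(roc_auc(exp(sc), lab)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(plogis(sc)), lab)$auc, a0, tolerance = 1e-9)
  expect_equal(roc_auc(sc^3, lab)$auc, a0, tolerance = 1e-12)
})

test_that("threshold table metrics and F1 follow their definitions", {
  tt <- threshold_table(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
                        thresholds = c(0, 2.5, 10))
  below <- tt[tt$threshold == 0, ]
  expect_equal(below$sensitivity, 1)
  expect_equal(below$specificity, 0)
  mid <- tt[tt$threshold == 2.5, ]
  expect_equal(mid[, c("sensitivity", "specificity", "ppv", "f1")],
               data.frame(sensitivity = 1, specificity = 1, ppv = 1, f1 = 1),
               ignore_attr = TRUE)
  above <- tt[tt$threshold == 10, ]
  expect_true(is.na(above$ppv))  # no positive predictions: undefined, not 0
  # the F1 formula: sens 0.8, ppv 0.5 -> 8/13
  f1 <- function(s, p) 2 * p * s / (p + s)
  expect_equal(f1(0.8, 0.5), 0.615385, tolerance = 1e-6)
})

test_that("prevalence-adjusted PPV follows Bayes' rule", {
  expect_equal(ppv_at_prevalence(0.9, 0.9, 0.5), 0.9)
  expect_equal(ppv_at_prevalence(0.9, 0.9, 0.1), 0.5)
  expect_equal(ppv_at_prevalence(0.7, 1, 0.2), 1)  # no false positives
  expect_true(is.na(ppv_at_prevalence(0, 1, 0.5)))
  expect_error(ppv_at_prevalence(1.2, 0.9, 0.1), "\\[0, 1\\]")
  # at the cohort's own prevalence it equals the empirical PPV
  set.seed(53)
  sc <- rnorm(400)
  lab <- runif(400) < plogis(2 * sc)
  prev <- mean(lab)
  tt <- threshold_table(sc, lab, thresholds = quantile(sc, c(.2, .5, .8)))
  ok <- !is.na(tt$ppv)
  expect_equal(ppv_at_prevalence(tt$sensitivity[ok], tt$specificity[ok], prev),
               tt$ppv[ok], tolerance = 1e-12)
})

test_that("net benefit reproduces its worked example and limits", {
  # 10 true positives, no false positives, per 100 patients: 0.1 at any pt
  for (pt in c(0.05, 0.2, 0.5, 0.9)) {
    expect_equal(net_benefit(tp = 10, fp = 0, n = 100, pt = pt), 0.1)
  }
  expect_equal(net_benefit(0, 0, 100, 0.3), 0)        # treat none
  expect_equal(net_benefit(50, 50, 100, 1 / 3), 0.25) # treat all, prevalence .5
  expect_error(net_benefit(10, 0, 100, 1), "\\(0, 1\\)")
  expect_error(net_benefit(60, 60, 100, 0.5))
})

test_that("decision curves behave like their reference strategies", {
  set.seed(54)
  n <- 400
  lab <- runif(n) < 0.316
  sc <- rnorm(n, mean = ifelse(lab, 2, 0))
  dc <- decision_curve(sc, lab, pt_grid = seq(0.05, 0.6, by = 0.05))
  expect_true(all(dc$treat_none == 0))
  # treat-all tends to prevalence as pt -> 0+
  tiny <- decision_curve(sc, lab, pt_grid = 0.001)
  expect_equal(tiny$treat_all, mean(lab), tolerance = 0.005)
  # the ideal marker's net benefit is the prevalence; no strategy beats it
  expect_true(all(dc$marker <= mean(lab) + 1e-12))
  expect_true(all(dc$treat_all <= mean(lab) + 1e-12))
  expect_identical(attr(dc, "calibration"), "logistic")
})

test_that("a perfectly separating marker dominates both reference strategies", {
  set.seed(55)
  lab <- rep(c(FALSE, TRUE), times = c(270, 130))
  sc <- ifelse(lab, runif(400, 10, 20), runif(400, 0, 5))
  dc <- decision_curve(sc, lab, pt_grid = seq(0.05, 0.6, by = 0.01))
  expect_identical(attr(dc, "calibration"), "empirical_quantile")
  expect_true(all(dc$marker >= dc$treat_all - 1e-12))
  expect_true(all(dc$marker >= dc$treat_none - 1e-12))
})

test_that("precision-recall curves enumerate the achieved operating points", {
  lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  sc <- c(3, 5, 1, 2, 4)
  pr <- precision_recall(sc, lab)
  pts <- pr$curve
  expect_true(any(pts$recall == 0.5 & pts$precision == 1))
  expect_true(any(pts$recall == 1 & abs(pts$precision - 2 / 3) < 1e-12))
  expect_equal(pr$n_dropped, 1L)  # the sweep point with no positive calls
  # perfect separation: area 1
  prf <- precision_recall(c(1, 2, 10, 11, 12), c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(prf$area, 1)
  # uninformative scores at large n: area near the prevalence baseline
  set.seed(56)
  lab2 <- runif(5000) < 0.3
  pr2 <- precision_recall(rnorm(5000), lab2)
  expect_lt(abs(pr2$area - mean(lab2)), 0.03)
  # prevalence reweighting lowers precision when prevalence drops
  pr3 <- precision_recall(sc, lab, prevalence = 0.1)
  expect_true(all(pr3$curve$precision_adj <= pr3$curve$precision + 1e-12))
  expect_lt(pr3$area_adj, pr3$area)
})

test_that("repeated stratified cross-validation is deterministic and calibrated", {
  set.seed(57)
  n <- 400
  lab <- runif(n) < 0.35
  sc <- rnorm(n, mean = ifelse(lab, 1.5, 0))
  cv1 <- repeated_cv_auc(sc, lab, k = 10, reps = 5, seed = 99)
  cv2 <- repeated_cv_auc(sc, lab, k = 10, reps = 5, seed = 99)
  expect_identical(cv1, cv2)
  expect_length(cv1$fold_aucs, 50)
  # perfectly separable: every fold AUC is 1
  sep <- repeated_cv_auc(c(rnorm(200), rnorm(200) + 100),
                         rep(c(FALSE, TRUE), each = 200), seed = 1)
  expect_equal(sep$mean_auc, 1)
  expect_equal(unname(diff(sep$interval)), 0)
  # under the null the interval straddles one half
  set.seed(58)
  null_cv <- repeated_cv_auc(rnorm(1000), runif(1000) < 0.4, seed = 3)
  expect_lt(null_cv$interval[1], 0.5)
  expect_gt(null_cv$interval[2], 0.5)
  # tiny cohorts and unstratifiable classes are rejected
  expect_error(repeated_cv_auc(rnorm(12), rep(c(TRUE, FALSE), 6), k = 10),
               "too small")
  expect_error(repeated_cv_auc(rnorm(40), rep(c(TRUE, FALSE), c(5, 35)),
                               k = 10), "stratified")
})
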