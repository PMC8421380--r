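#' ROC curve and AUC with 95% confidence interval
#'
#' The AUC equals the probability that a random positive outscores a random
#' negative, with ties counted one half (Mann-Whitney identity; the ROC curve
#' is trapezoidal). The confidence interval uses DeLong's method by default,
#' or a seeded percentile bootstrap.
#'
#' @param score numeric marker values (higher = more AF-like); `NA` entries
#'   (unevaluable recordings) are dropped and counted.
#' @param label logical ECG ground truth, same length.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n bootstrap resamples (bootstrap method only).
#' @param seed seed used for the bootstrap CI; ignored for DeLong.
#' @return list of class `roc_result`: `auc`, `ci` (lower, upper), `curve`
#'   (data.frame `fpr`, `tpr`, `threshold`), `n`, `n_dropped`.
#' @examples
#' roc_auc(c(1, 2, 4, 3, 5), c(FALSE, FALSE, FALSE, TRUE, TRUE))$auc  # 5/6
#' @export
roc_auc <- function(score, label, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(score) & !is.na(label)
  n_dropped <- sum(!keep)
  score <- score[keep]
  label <- as.logical(label[keep])
  if (length(unique(label)) < 2L) {
    stop("degenerate cohort: both AF and non-AF labels are required",
         call. = FALSE)
  }
  r <- pROC::roc(response = label, predictor = score,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  # pROC warns that the CI of an AUC of exactly 1 is degenerate; that is
  # expected on separable cohorts
  ci <- suppressWarnings(if (ci_method == "delong") {
    pROC::ci.auc(r, method = "delong")
  } else {
    set.seed(seed)
    pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n, progress = "none")
  })
  structure(list(
    auc = as.numeric(pROC::auc(r)),
    ci = c(lower = as.numeric(ci[1L]), upper = as.numeric(ci[3L])),
    curve = data.frame(fpr = rev(1 - r$specificities),
                       tpr = rev(r$sensitivities),
                       threshold = rev(r$thresholds)),
    n = length(score), n_dropped = n_dropped
  ), class = "roc_result")
}

# AUC alone, for fold-level cross-validation use.
auc_value <- function(score, label) {
  as.numeric(pROC::auc(pROC::roc(
    response = as.logical(label), predictor = score,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
}

#' Threshold-specific diagnostic metrics for a continuous marker
#'
#' At each threshold the prediction is `score > threshold` (strict), the
#' 2 x 2 table is formed, and [diagnostic_metrics()] plus the F1 score
#' (harmonic mean of sensitivity and PPV) are reported. `NA` scores are
#' excluded from all denominators.
#'
#' @inheritParams roc_auc
#' @param thresholds numeric vector of cut-points.
#' @return data.frame: `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`, `f1` (undefined metrics are `NA`).
#' @export
threshold_table <- function(score, label, thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L)
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]
  label <- as.logical(label[keep])
  rows <- lapply(thresholds, function(t) {
    pred <- score > t
    ct <- list(tp = sum(pred & label), fp = sum(pred & !label),
               tn = sum(!pred & !label), fn = sum(!pred & label))
    m <- diagnostic_metrics(ct)
    f1 <- if (is.na(m$ppv) || is.na(m$sensitivity) ||
              (m$ppv + m$sensitivity) == 0) NA_real_
          else 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity)
    data.frame(threshold = t, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv, npv = m$npv,
               accuracy = m$accuracy, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Positive predictive value at a stated prevalence
#'
#' Bayes' rule for a test with the given sensitivity and specificity applied
#' in a population with the given AF prevalence; used to translate in-sample
#' precision to a less targeted screening population (e.g. 10% prevalence).
#'
#' @param sensitivity,specificity,prevalence proportions in \[0, 1\]
#'   (vectorised).
#' @return PPV; `NA` where the positive-prediction rate is zero.
#' @examples
#' ppv_at_prevalence(0.9, 0.9, 0.1)  # 0.5
#' @export
ppv_at_prevalence <- function(sensitivity, specificity, prevalence) {
  args <- cbind(sensitivity, specificity, prevalence)
  if (any(args < 0 | args > 1, na.rm = TRUE)) {
    stop("sensitivity, specificity and prevalence must lie in [0, 1]",
         call. = FALSE)
  }
  num <- sensitivity * prevalence
  den <- num + (1 - specificity) * (1 - prevalence)
  ifelse(den > 0, num / den, NA_real_)
}

#' Net benefit of a screening strategy at a threshold probability
#'
#' `tp/n - (fp/n) * pt/(1 - pt)`: true positives per patient minus false
#' positives weighted by the odds of the threshold probability `pt` (the
#' exchange rate between benefit and harm implied by the clinical
#' preference). A net benefit of 0.1 means 10 more benefits than harms per
#' 100 patients.
#'
#' @param tp,fp true- and false-positive counts of the strategy.
#' @param n cohort size (`tp + fp <= n`).
#' @param pt threshold probability in (0, 1) (vectorised).
#' @return net benefit (dimensionless).
#' @examples
#' net_benefit(tp = 10, fp = 0, n = 100, pt = 0.3)  # 0.1
#' @export
net_benefit <- function(tp, fp, n, pt) {
  stopifnot(tp >= 0, fp >= 0, n > 0, tp + fp <= n)
  if (any(!is.finite(pt) | pt <= 0 | pt >= 1)) {
    stop("`pt` must lie strictly inside (0, 1)", call. = FALSE)
  }
  tp / n - (fp / n) * pt / (1 - pt)
}

#' Decision curve for a continuous marker
#'
#' The marker is mapped to a predicted AF probability by univariate logistic
#' calibration; at each threshold probability `pt`, participants with
#' predicted probability >= `pt` screen positive and the net benefit is
#' computed, alongside the treat-all and treat-none reference strategies.
#' If the logistic fit separates completely, the mapping falls back to the
#' empirical quantile of the score (flagged in the `calibration` attribute).
#'
#' @inheritParams roc_auc
#' @param pt_grid threshold probabilities, all inside (0, 1).
#' @return data.frame of class `decision_curve`: `pt`, `marker`,
#'   `treat_all`, `treat_none`; attribute `calibration` records the mapping
#'   used.
#' @export
decision_curve <- function(score, label, pt_grid = seq(0.05, 0.60, by = 0.01)) {
  if (any(pt_grid <= 0 | pt_grid >= 1)) {
    stop("`pt_grid` must lie strictly inside (0, 1)", call. = FALSE)
  }
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]
  label <- as.logical(label[keep])
  n <- length(score)
  if (length(unique(label)) < 2L) {
    stop("degenerate cohort: both AF and non-AF labels are required",
         call. = FALSE)
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(label ~ score, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  p <- if (separated) {
    (rank(score, ties.method = "average") - 0.5) / n
  } else {
    as.numeric(stats::fitted(fit))
  }
  rows <- vapply(pt_grid, function(pt) {
    pred <- p >= pt
    c(marker = net_benefit(sum(pred & label), sum(pred & !label), n, pt),
      treat_all = net_benefit(sum(label), sum(!label), n, pt))
  }, numeric(2))
  out <- data.frame(pt = pt_grid, marker = rows["marker", ],
                    treat_all = rows["treat_all", ], treat_none = 0)
  attr(out, "calibration") <- if (separated) "empirical_quantile" else "logistic"
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' Precision-recall curve with area
#'
#' Operating points are generated by sweeping the threshold over the achieved
#' score values (strict `>` classification, matching [classify_single()]);
#' points with no positive predictions have undefined precision and are
#' dropped (their number is recorded). The area is the trapezoid over the
#' achieved points, anchored at recall 0 with the precision of the most
#' stringent achieved point. With `prevalence` given, a second curve rescales
#' each point's precision to that prevalence via [ppv_at_prevalence()].
#'
#' @inheritParams roc_auc
#' @param prevalence optional prevalence for the reweighted curve.
#' @return list of class `pr_curve`: `curve` (data.frame `threshold`,
#'   `recall`, `precision`, and `precision_adj` if requested), `area`,
#'   `area_adj` (or `NULL`), `baseline` (cohort prevalence), `n_dropped`.
#' @export
precision_recall <- function(score, label, prevalence = NULL) {
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]
  label <- as.logical(label[keep])
  if (length(unique(label)) < 2L) {
    stop("degenerate cohort: both AF and non-AF labels are required",
         call. = FALSE)
  }
  ts <- c(sort(unique(score), decreasing = TRUE), -Inf)
  n_pos <- sum(label)
  n_neg <- sum(!label)
  rows <- lapply(ts, function(t) {
    pred <- score > t
    npp <- sum(pred)
    if (npp == 0) return(NULL)
    data.frame(threshold = t,
               recall = sum(pred & label) / n_pos,
               precision = sum(pred & label) / npp,
               specificity = 1 - sum(pred & !label) / n_neg)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  curve <- do.call(rbind, rows)
  # anchor at recall 0 with the most stringent achieved precision
  anchor <- curve[1L, , drop = FALSE]
  anchor$recall <- 0
  anchor$threshold <- Inf
  curve <- rbind(anchor, curve)
  if (!is.null(prevalence)) {
    curve$precision_adj <- ppv_at_prevalence(curve$recall, curve$specificity,
                                             prevalence)
    # the recall-0 anchor reuses the first achieved point's adjusted precision
    curve$precision_adj[1L] <-
      ppv_at_prevalence(curve$recall[2L], curve$specificity[2L], prevalence)
  }
  trap <- function(x, y) {
    dx <- diff(x)
    sum(dx * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  out <- list(curve = curve[, setdiff(names(curve), "specificity")],
              area = trap(curve$recall, curve$precision),
              area_adj = if (is.null(prevalence)) NULL
                         else trap(curve$recall, curve$precision_adj),
              baseline = n_pos / (n_pos + n_neg),
              n_dropped = dropped)
  class(out) <- "pr_curve"
  out
}

#' Repeated stratified k-fold cross-validated AUC
#'
#' Folds are stratified by label; the AUC is re-estimated on each held-out
#' fold (there is no tunable model: the marker value itself is the score).
#' Reported are the mean and the 2.5/97.5 percentiles across all k x reps
#' fold AUCs.
#'
#' @inheritParams roc_auc
#' @param k number of folds (default 10).
#' @param reps number of repetitions (default 10).
#' @param seed seed for fold assignment.
#' @return list of class `cv_auc`: `mean_auc`, `interval` (2.5% and 97.5%
#'   percentiles), `fold_aucs`.
#' @export
repeated_cv_auc <- function(score, label, k = 10, reps = 10, seed = 1L) {
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]
  label <- as.logical(label[keep])
  n <- length(score)
  if (n < 2 * k) stop("cohort too small for ", k, "-fold cross-validation",
                      call. = FALSE)
  if (sum(label) < k || sum(!label) < k) {
    stop("each class needs at least k members for stratified folds",
         call. = FALSE)
  }
  set.seed(seed)
  fold_aucs <- numeric(0)
  idx_pos <- which(label)
  idx_neg <- which(!label)
  for (r in seq_len(reps)) {
    fold <- integer(n)
    fold[idx_pos] <- sample(rep_len(seq_len(k), length(idx_pos)))
    fold[idx_neg] <- sample(rep_len(seq_len(k), length(idx_neg)))
    for (f in seq_len(k)) {
      held <- fold == f
      fold_aucs <- c(fold_aucs, auc_value(score[held], label[held]))
    }
  }
  structure(list(
    mean_auc = mean(fold_aucs),
    interval = stats::quantile(fold_aucs, c(0.025, 0.975), names = TRUE),
    fold_aucs = fold_aucs
  ), class = "cv_auc")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), n = %d\n",
              x$auc, x$ci[1L], x$ci[2L], x$n))
  invisible(x)
}

#' @export
print.cv_auc <- function(x, ...) {
  cat(sprintf("<cv_auc> mean AUC %.3f (%.3f-%.3f across %d fold estimates)\n",
              x$mean_auc, x$interval[1L], x$interval[2L], length(x$fold_aucs)))
  invisible(x)
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> area %.3f (baseline prevalence %.3f), %d points\n",
              x$area, x$baseline, nrow(x$curve)))
  invisible(x)
}
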