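#' Cross-tabulate device labels against ECG ground truth
#'
#' @param absent,present integer vectors of length 4: label counts
#'   (`normal`, `possible_af`, `unclassified`, `blank`) among ECG-AF-absent
#'   and ECG-AF-present participants.
#' @return A 2 x 4 integer matrix of class `kmcm_crosstab`, rows
#'   `absent`/`present`, columns [kmcm_labels].
#' @examples
#' # A screening cohort: 288 non-AF, 133 AF participants
#' kmcm_crosstab(absent = c(195, 23, 57, 13), present = c(3, 111, 15, 4))
#' @export
kmcm_crosstab <- function(absent, present) {
  stopifnot(length(absent) == 4L, length(present) == 4L)
  m <- rbind(absent = as.numeric(absent), present = as.numeric(present))
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("cross-tab counts must be non-negative integers", call. = FALSE)
  }
  colnames(m) <- kmcm_labels
  structure(m, class = c("kmcm_crosstab", "matrix", "array"))
}

#' @describeIn kmcm_crosstab Build the cross-tab from a cohort participants
#'   table (columns `ecg_af`, `kmcm_label`).
#' @param participants data.frame with logical `ecg_af` and `kmcm_label` in
#'   [kmcm_labels].
#' @export
kmcm_crosstab_from_cohort <- function(participants) {
  stopifnot(all(c("ecg_af", "kmcm_label") %in% names(participants)))
  lab <- factor(participants$kmcm_label, levels = kmcm_labels)
  if (anyNA(lab)) stop("unknown device label in cohort", call. = FALSE)
  counts <- table(ifelse(participants$ecg_af, "present", "absent"), lab)
  get_row <- function(r) if (r %in% rownames(counts)) as.numeric(counts[r, ]) else rep(0, 4)
  kmcm_crosstab(absent = get_row("absent"), present = get_row("present"))
}

#' Collapse a label cross-tab to a 2 x 2 contingency table
#'
#' Two policies handle `unclassified` and `blank` ("unreadable") output:
#' `penalise_unreadable` deems every unreadable recording incorrect (counted
#' as a false negative among AF cases and a false positive among non-AF),
#' while `exclude_unreadable` drops those recordings before forming the 2 x 2.
#'
#' @param xtab a [kmcm_crosstab()].
#' @param policy `"penalise_unreadable"` or `"exclude_unreadable"`.
#' @return list of class `contingency_table`: `tp`, `fp`, `tn`, `fn`,
#'   `policy`.
#' @export
build_contingency <- function(xtab,
                              policy = c("penalise_unreadable",
                                         "exclude_unreadable")) {
  policy <- match.arg(policy)
  stopifnot(inherits(xtab, "kmcm_crosstab"))
  pres <- xtab["present", ]
  abs_ <- xtab["absent", ]
  ct <- if (policy == "penalise_unreadable") {
    list(tp = pres[["possible_af"]],
         fp = abs_[["possible_af"]] + abs_[["unclassified"]] + abs_[["blank"]],
         tn = abs_[["normal"]],
         fn = pres[["normal"]] + pres[["unclassified"]] + pres[["blank"]])
  } else {
    list(tp = pres[["possible_af"]],
         fp = abs_[["possible_af"]],
         tn = abs_[["normal"]],
         fn = pres[["normal"]])
  }
  ct$policy <- policy
  class(ct) <- "contingency_table"
  ct
}

#' Diagnostic metrics from a 2 x 2 contingency table
#'
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' as 0.
#'
#' @param ct a `contingency_table` (see [build_contingency()]) or any list
#'   with fields `tp`, `fp`, `tn`, `fn`.
#' @return named list of proportions: `sensitivity`, `specificity`,
#'   `accuracy`, `ppv`, `npv`.
#' @export
diagnostic_metrics <- function(ct) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  with(ct, list(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy    = safe_div(tp + tn, tp + fp + tn + fn),
    ppv         = safe_div(tp, tp + fp),
    npv         = safe_div(tn, tn + fn)
  ))
}

#' Breakdown of AF cases the device failed to detect
#'
#' An AF case is "undetected" when its label is anything but `possible_af`;
#' "unreadable" means `unclassified` or `blank`.
#'
#' @param xtab a [kmcm_crosstab()].
#' @return list: `undetected_fraction` (of all AF cases),
#'   `frac_unclassified_of_undetected`, `frac_unreadable_of_undetected`
#'   (both `NA` when nothing was undetected), and the counts `n_af`,
#'   `n_undetected`.
#' @export
undetected_breakdown <- function(xtab) {
  stopifnot(inherits(xtab, "kmcm_crosstab"))
  pres <- xtab["present", ]
  n_af <- sum(pres)
  if (n_af == 0) stop("no AF cases in cross-tab", call. = FALSE)
  undetected <- n_af - pres[["possible_af"]]
  list(
    undetected_fraction = undetected / n_af,
    frac_unclassified_of_undetected =
      if (undetected > 0) pres[["unclassified"]] / undetected else NA_real_,
    frac_unreadable_of_undetected =
      if (undetected > 0) (pres[["unclassified"]] + pres[["blank"]]) / undetected
      else NA_real_,
    n_af = n_af,
    n_undetected = undetected
  )
}

#' Device performance report under both unreadable-output policies
#'
#' One row per policy with raw proportions and whole-percent values (rounded
#' half-up, the presentation convention for screening tables), plus the
#' readable/unreadable recording counts.
#'
#' @param xtab a [kmcm_crosstab()].
#' @return data.frame with columns `policy`, `n`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`, `ppv`, `npv` and their
#'   `*_pct` rounded counterparts.
#' @export
kmcm_report <- function(xtab) {
  stopifnot(inherits(xtab, "kmcm_crosstab"))
  rows <- lapply(c("penalise_unreadable", "exclude_unreadable"), function(p) {
    ct <- build_contingency(xtab, p)
    m <- diagnostic_metrics(ct)
    data.frame(policy = p, n = ct$tp + ct$fp + ct$tn + ct$fn,
               tp = ct$tp, fp = ct$fp, tn = ct$tn, fn = ct$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy, ppv = m$ppv, npv = m$npv,
               sensitivity_pct = round_half_up(100 * m$sensitivity),
               specificity_pct = round_half_up(100 * m$specificity),
               accuracy_pct = round_half_up(100 * m$accuracy),
               ppv_pct = round_half_up(100 * m$ppv),
               npv_pct = round_half_up(100 * m$npv))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_unreadable") <-
    sum(xtab[, c("unclassified", "blank")])
  attr(out, "n_readable") <- sum(xtab) - attr(out, "n_unreadable")
  out
}

#' Round half away from zero
#'
#' Presentation rounding for report percentages (base `round()` rounds half
#' to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> policy=%s  tp=%g fp=%g tn=%g fn=%g\n",
              x$policy, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
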