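#' @rdname classify_combined
#' @export
combination_rules <- c("first_only", "mean_of_two", "both_exceed",
                       "first_and_kmcm", "mean_and_kmcm", "banded")

#' Threshold classification of a single PRV value
#'
#' Strict exceedance: the prediction is positive iff `value > threshold`
#' (a value exactly at the threshold is negative). A missing value (e.g. a
#' recording with insufficient beats) yields `NA` — "unevaluable", distinct
#' from a negative prediction; unevaluable records are excluded from metric
#' denominators downstream.
#'
#' @param value PRV statistic value(s); `NA` allowed.
#' @param threshold cut-point in the same units.
#' @return logical vector (with `NA` for unevaluable inputs).
#' @export
classify_single <- function(value, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  value > threshold
}

#' Combination-rule AF prediction from one or two readings and a device label
#'
#' Implements the screening strategies built from two sequential PRV readings
#' and the rhythm-monitor label:
#' \describe{
#'   \item{first_only}{first reading exceeds the threshold.}
#'   \item{mean_of_two}{the mean of the two readings exceeds it.}
#'   \item{both_exceed}{both readings exceed it.}
#'   \item{first_and_kmcm}{first reading exceeds it AND the device label is
#'     not "normal" (unclassified and blank both count as not normal).}
#'   \item{mean_and_kmcm}{mean of two exceeds it AND label not "normal".}
#'   \item{banded}{if the first reading lies strictly inside the uncertainty
#'     band `(band[1], band[2])`, the confirmatory rule decides; outside the
#'     band the first reading alone decides. A degenerate band with
#'     `band[1] == band[2]` is empty, so the rule reduces to `first_only`.}
#' }
#' All comparisons are strict (`>`). Inputs required by the chosen rule but
#' absent (`NULL` argument or `NA` element) make that prediction `NA`
#' ("unevaluable").
#'
#' @param r1 first-reading PRV values.
#' @param r2 second-reading PRV values, or `NULL` if none were taken.
#' @param kmcm_label character vector of device labels ([kmcm_labels]), or
#'   `NULL`.
#' @param rule one of `combination_rules`.
#' @param threshold scalar cut-point (units of the PRV statistic).
#' @param band length-2 numeric, uncertainty band for `banded`
#'   (default `c(6, 14)`, the percent band where single-reading predictions
#'   are least reliable).
#' @param confirm_rule rule applied inside the band (default `both_exceed`);
#'   must not itself be `banded`.
#' @return logical vector of predictions, `NA` where unevaluable.
#' @examples
#' classify_combined(10, 2, rule = "both_exceed", threshold = 6)   # FALSE
#' classify_combined(10, 2, rule = "first_only", threshold = 6)    # TRUE
#' @export
classify_combined <- function(r1, r2 = NULL, kmcm_label = NULL,
                              rule = combination_rules, threshold,
                              band = c(6, 14),
                              confirm_rule = "both_exceed") {
  rule <- match.arg(rule)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  n <- length(r1)
  need_r2 <- rule %in% c("mean_of_two", "both_exceed", "mean_and_kmcm") ||
    (rule == "banded" &&
       confirm_rule %in% c("mean_of_two", "both_exceed", "mean_and_kmcm"))
  need_label <- rule %in% c("first_and_kmcm", "mean_and_kmcm") ||
    (rule == "banded" && confirm_rule %in% c("first_and_kmcm", "mean_and_kmcm"))
  if (need_r2 && is.null(r2)) {
    stop(sprintf("rule '%s' needs a second reading but none was supplied", rule),
         call. = FALSE)
  }
  if (need_label && is.null(kmcm_label)) {
    stop(sprintf("rule '%s' needs a device label but none was supplied", rule),
         call. = FALSE)
  }
  if (!is.null(r2)) stopifnot(length(r2) == n)
  if (!is.null(kmcm_label)) {
    stopifnot(length(kmcm_label) == n)
    bad <- !is.na(kmcm_label) & !kmcm_label %in% kmcm_labels
    if (any(bad)) {
      stop("unknown device label(s): ",
           paste(unique(kmcm_label[bad]), collapse = ", "), call. = FALSE)
    }
  }
  not_normal <- if (is.null(kmcm_label)) NULL else kmcm_label != "normal"

  eval_rule <- function(rl) {
    switch(rl,
      first_only     = r1 > threshold,
      mean_of_two    = (r1 + r2) / 2 > threshold,
      both_exceed    = r1 > threshold & r2 > threshold,
      first_and_kmcm = r1 > threshold & not_normal,
      mean_and_kmcm  = (r1 + r2) / 2 > threshold & not_normal
    )
  }

  if (rule != "banded") return(eval_rule(rule))

  confirm_rule <- match.arg(confirm_rule,
                            setdiff(combination_rules, "banded"))
  stopifnot(is.numeric(band), length(band) == 2L, band[1] <= band[2])
  uncertain <- !is.na(r1) & r1 > band[1] & r1 < band[2]
  out <- r1 > threshold
  confirmed <- eval_rule(confirm_rule)
  out[uncertain] <- confirmed[uncertain]
  out
}
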