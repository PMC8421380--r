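#' Beat-exclusion pre-filter for a pulse-interval series
#'
#' Removes intervals whose duration deviates from the mean beat duration of
#' the raw series by more than `exclusion_fraction` of that mean.  The band is
#' centred on the raw-series mean, computed once (no iterative re-meaning).
#' This pre-filter reduces false positives from ectopic beats before the
#' variability statistics are computed.
#'
#' @param intervals numeric vector of beat-to-beat intervals in milliseconds,
#'   in acquisition order, all > 0, length >= 2.
#' @param exclusion_fraction half-width of the acceptance band as a fraction
#'   of the mean interval, in (0, 1]. Default 0.25; 0.25--0.30 is the usual
#'   operating range.
#' @return The surviving intervals, original order preserved, with attribute
#'   `n_excluded` giving the number of removed beats.
#' @examples
#' filter_beats(c(800, 800, 800, 1200))  # 1200 excluded (band 675--1125)
#' @export
filter_beats <- function(intervals, exclusion_fraction = 0.25) {
  check_intervals(intervals, min_n = 2)
  if (!is.numeric(exclusion_fraction) || length(exclusion_fraction) != 1L ||
      !is.finite(exclusion_fraction) ||
      exclusion_fraction <= 0 || exclusion_fraction > 1) {
    stop("`exclusion_fraction` must be a single number in (0, 1]", call. = FALSE)
  }
  m <- mean(intervals)
  keep <- abs(intervals - m) <= exclusion_fraction * m
  out <- intervals[keep]
  if (length(out) < 2L) {
    insufficient_beats(sprintf(
      "only %d interval(s) survive the %.0f%% exclusion band",
      length(out), 100 * exclusion_fraction))
  }
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Standardised average real variability (sARV)
#'
#' Mean absolute successive pulse-interval difference as a percentage of the
#' mean interval of the series.  Scale-free: multiplying all intervals by a
#' positive constant leaves sARV unchanged.
#'
#' @inheritParams filter_beats
#' @return sARV in percent.
#' @examples
#' sarv(c(700, 900, 700))  # 26.09
#' @export
sarv <- function(intervals) {
  check_intervals(intervals, min_n = 2)
  100 * mean(abs(diff(intervals))) / mean(intervals)
}

#' Root mean square of successive differences (RMSSD)
#'
#' @inheritParams filter_beats
#' @return RMSSD in milliseconds.
#' @examples
#' rmssd(c(700, 900, 700))  # 200
#' @export
rmssd <- function(intervals) {
  check_intervals(intervals, min_n = 2)
  sqrt(mean(diff(intervals)^2))
}

#' Pulse-interval standard deviation
#'
#' Sample standard deviation (n - 1 denominator, the convention in
#' heart-rate-variability work with short recordings).
#'
#' @inheritParams filter_beats
#' @return SD in milliseconds.
#' @export
interval_sd <- function(intervals) {
  check_intervals(intervals, min_n = 2)
  stats::sd(intervals)
}

#' Coefficient of variation (irregularity index)
#'
#' Interval standard deviation as a percentage of the mean interval.
#'
#' @inheritParams filter_beats
#' @return CV in percent.
#' @export
interval_cv <- function(intervals) {
  check_intervals(intervals, min_n = 2)
  100 * stats::sd(intervals) / mean(intervals)
}

#' Relative range of pulse intervals
#'
#' (max - min) / mean, as a percentage.
#'
#' @inheritParams filter_beats
#' @return relative range in percent.
#' @export
relative_range <- function(intervals) {
  check_intervals(intervals, min_n = 2)
  100 * (max(intervals) - min(intervals)) / mean(intervals)
}

#' Irregular pulse percentage (IPP)
#'
#' Percentage of beats whose duration deviates from the mean beat duration by
#' more than `ipp_fraction` of that mean.  Applied to the raw, unfiltered
#' series: the beat-exclusion pre-filter is used only for the remaining
#' statistics, while IPP itself counts the aberrant beats.
#'
#' @inheritParams filter_beats
#' @param ipp_fraction irregularity band half-width as a fraction of the mean
#'   interval, in (0, 1]. Default 0.15 (the +/- 15 percent rule).
#' @return IPP in percent, in \[0, 100\].
#' @examples
#' ipp(c(800, 800, 800, 1000))  # 25
#' @export
ipp <- function(intervals, ipp_fraction = 0.15) {
  check_intervals(intervals, min_n = 1)
  if (!is.numeric(ipp_fraction) || length(ipp_fraction) != 1L ||
      !is.finite(ipp_fraction) || ipp_fraction <= 0 || ipp_fraction > 1) {
    stop("`ipp_fraction` must be a single number in (0, 1]", call. = FALSE)
  }
  m <- mean(intervals)
  100 * sum(abs(intervals - m) > ipp_fraction * m) / length(intervals)
}

#' Compute all six PRV statistics for one recording
#'
#' sARV, RMSSD, SD, CV and relative range are computed on the
#' exclusion-filtered series; IPP on the raw series.  A recording with fewer
#' than 8 raw beats is flagged as low pulse rate (the < 48 beats/minute proxy
#' over a ~10 s recording).
#'
#' @inheritParams filter_beats
#' @param ipp_fraction see [ipp()].
#' @return A one-row `data.frame` with columns `sarv`, `rmssd`, `sd`, `cv`,
#'   `relative_range`, `ipp`, `n_beats_raw`, `n_beats_used`, `low_beat_flag`.
#' @seealso [compute_prv_table()] for whole-cohort computation with
#'   per-recording error recovery.
#' @export
compute_prv <- function(intervals, exclusion_fraction = 0.25,
                        ipp_fraction = 0.15) {
  check_intervals(intervals, min_n = 2)
  filtered <- filter_beats(intervals, exclusion_fraction)
  data.frame(
    sarv           = sarv(filtered),
    rmssd          = rmssd(filtered),
    sd             = interval_sd(filtered),
    cv             = interval_cv(filtered),
    relative_range = relative_range(filtered),
    ipp            = ipp(intervals, ipp_fraction),
    n_beats_raw    = length(intervals),
    n_beats_used   = length(filtered),
    low_beat_flag  = length(intervals) < 8L
  )
}

#' Compute PRV statistics for every recording in a long-format interval table
#'
#' "Insufficient beats" is a recoverable per-recording condition: the affected
#' recording gets `NA` statistics and `status = "insufficient_beats"` while
#' the rest of the cohort is processed normally.
#'
#' @param intervals_df data.frame with columns `participant_id`,
#'   `reading_index`, `beat_index`, `interval_ms` (see [read_intervals()]).
#' @inheritParams compute_prv
#' @return A `data.frame` with one row per (participant, reading): identity
#'   columns, the [compute_prv()] columns, and `status` ("ok" or
#'   "insufficient_beats").
#' @export
compute_prv_table <- function(intervals_df, exclusion_fraction = 0.25,
                              ipp_fraction = 0.15) {
  stopifnot(is.data.frame(intervals_df))
  needed <- c("participant_id", "reading_index", "interval_ms")
  missing_cols <- setdiff(needed, names(intervals_df))
  if (length(missing_cols)) {
    stop("interval table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if ("beat_index" %in% names(intervals_df)) {
    o <- order(intervals_df$participant_id, intervals_df$reading_index,
               intervals_df$beat_index)
    intervals_df <- intervals_df[o, , drop = FALSE]
  }
  key <- interaction(intervals_df$participant_id, intervals_df$reading_index,
                     drop = TRUE, lex.order = TRUE)
  pieces <- split(intervals_df, key)
  na_row <- data.frame(sarv = NA_real_, rmssd = NA_real_, sd = NA_real_,
                       cv = NA_real_, relative_range = NA_real_,
                       ipp = NA_real_, n_beats_raw = NA_integer_,
                       n_beats_used = NA_integer_, low_beat_flag = NA)
  rows <- lapply(pieces, function(p) {
    res <- tryCatch(
      compute_prv(p$interval_ms, exclusion_fraction, ipp_fraction),
      prvscreen_insufficient_beats = function(e) e
    )
    if (inherits(res, "condition")) {
      out <- na_row
      out$n_beats_raw <- length(p$interval_ms)
      out$status <- "insufficient_beats"
    } else {
      out <- res
      out$status <- "ok"
    }
    cbind(data.frame(participant_id = p$participant_id[1L],
                     reading_index = p$reading_index[1L]), out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shared validation: positive finite numeric intervals, minimum length.
check_intervals <- function(intervals, min_n) {
  if (!is.numeric(intervals)) {
    stop("intervals must be numeric (milliseconds)", call. = FALSE)
  }
  if (anyNA(intervals) || any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("intervals must all be positive finite durations", call. = FALSE)
  }
  if (length(intervals) < min_n) {
    insufficient_beats(sprintf("need at least %d interval(s), got %d",
                               min_n, length(intervals)))
  }
  invisible(intervals)
}

insufficient_beats <- function(msg) {
  stop(structure(
    class = c("prvscreen_insufficient_beats", "error", "condition"),
    list(message = paste0("insufficient beats: ", msg), call = NULL)
  ))
}
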