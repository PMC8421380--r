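#' @title KMCM label levels
#' @description The four outputs of the single-lead rhythm monitor, in
#'   canonical order. "blank" is an explicit token meaning no analysis could
#'   be produced; it is never serialised as an empty cell.
#' @export
kmcm_labels <- c("normal", "possible_af", "unclassified", "blank")

#' @rdname cohort_config
#' @export
rhythm_classes <- c("sinus", "af", "sinus_with_ectopy", "af_paced")

# Study-calibrated defaults: cohort margins conditional on ECG AF status.
default_kmcm_confusion <- function() {
  m <- rbind(absent  = c(195, 23, 57, 13) / 288,
             present = c(3, 111, 15, 4) / 133)
  colnames(m) <- kmcm_labels
  m
}

default_subgroup_probs <- function() {
  # columns: P(flag | AF absent), P(flag | AF present)
  rbind(prior_af_diagnosis = c(80 / 288, 124 / 133),
        age_ge_65          = c(314 / 421, 314 / 421),
        af_risk_ge_5pct    = c(185 / 288, 71 / 133),
        high_chads2        = c(219 / 288, 84 / 133),
        high_cha2ds2vasc   = c(274 / 288, 130 / 133))
}

#' Configuration for the synthetic AF screening cohort
#'
#' Defaults reproduce the margins of a primary-care AF screening population:
#' AF prevalence 133/421, interval-series coefficients of variation of 2.1%
#' (sinus) and 12.6% (AF), mean ECG heart rates 70 and 76 beats/min, rhythm
#' monitor label frequencies matching the published class-conditional
#' confusion counts, and subgroup flag frequencies conditional on AF status.
#'
#' @param n_participants number of participants (>= 2).
#' @param af_prevalence probability a participant is ECG-AF-positive.
#' @param sinus_cv_pct,af_cv_pct target coefficient of variation (percent) of
#'   the interval series for sinus rhythm and AF.
#' @param mean_hr_sinus,mean_hr_af,hr_sd_bpm between-participant heart-rate
#'   distribution (beats/min), by AF status.
#' @param ectopy_fraction fraction of non-AF participants whose rhythm is
#'   sinus with ectopy (premature-compensatory beat pairs).
#' @param ectopy_rate per-beat probability that an ectopic pair starts at that
#'   beat, within an ectopy participant's recording (at least one pair is
#'   always placed). Setting this to 0 disables the ectopy class entirely.
#' @param paced_fraction_of_af fraction of AF participants with a paced,
#'   near-regular rhythm. 0 disables the class.
#' @param paced_cv_pct interval CV (percent) for paced rhythm (<= 0.5).
#' @param recording_duration_s length of each recording window in seconds.
#' @param kmcm_confusion 2 x 4 matrix of label probabilities, rows
#'   `absent`/`present` (ECG AF status), columns [kmcm_labels]; rows sum to 1.
#' @param inter_reading_jitter relative standard deviation applied to a
#'   participant's mean interval between the first and second reading
#'   (readings are ~95 s apart, so rhythm parameters drift slightly).
#' @param subgroup_probs 5 x 2 matrix of subgroup flag probabilities
#'   (rows `prior_af_diagnosis`, `age_ge_65`, `af_risk_ge_5pct`,
#'   `high_chads2`, `high_cha2ds2vasc`; columns P(flag | AF absent),
#'   P(flag | AF present)).
#' @param seed root seed; per-participant substreams are derived from it
#'   deterministically so cohorts are reproducible.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 421,
                          af_prevalence = 133 / 421,
                          sinus_cv_pct = 2.1,
                          af_cv_pct = 12.6,
                          mean_hr_sinus = 70,
                          mean_hr_af = 76,
                          hr_sd_bpm = 15,
                          ectopy_fraction = 42 / 288,
                          ectopy_rate = 0.15,
                          paced_fraction_of_af = 7 / 133,
                          paced_cv_pct = 0.2,
                          recording_duration_s = 10,
                          kmcm_confusion = default_kmcm_confusion(),
                          inter_reading_jitter = 0.02,
                          subgroup_probs = default_subgroup_probs(),
                          seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              af_prevalence = af_prevalence,
              sinus_cv_pct = sinus_cv_pct, af_cv_pct = af_cv_pct,
              mean_hr_sinus = mean_hr_sinus, mean_hr_af = mean_hr_af,
              hr_sd_bpm = hr_sd_bpm,
              ectopy_fraction = ectopy_fraction, ectopy_rate = ectopy_rate,
              paced_fraction_of_af = paced_fraction_of_af,
              paced_cv_pct = paced_cv_pct,
              recording_duration_s = recording_duration_s,
              kmcm_confusion = kmcm_confusion,
              inter_reading_jitter = inter_reading_jitter,
              subgroup_probs = subgroup_probs,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_participants) || cfg$n_participants < 2L) {
    stop("`n_participants` must be >= 2", call. = FALSE)
  }
  probs <- c(af_prevalence = cfg$af_prevalence,
             ectopy_fraction = cfg$ectopy_fraction,
             ectopy_rate = cfg$ectopy_rate,
             paced_fraction_of_af = cfg$paced_fraction_of_af)
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad)) {
    stop("probabilities out of [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cvs <- c(cfg$sinus_cv_pct, cfg$af_cv_pct, cfg$paced_cv_pct)
  if (any(!is.finite(cvs) | cvs < 0)) {
    stop("coefficients of variation must be non-negative", call. = FALSE)
  }
  pos <- c(cfg$mean_hr_sinus, cfg$mean_hr_af, cfg$hr_sd_bpm,
           cfg$recording_duration_s)
  if (any(!is.finite(pos) | pos <= 0)) {
    stop("heart rates, their dispersion and recording duration must be positive",
         call. = FALSE)
  }
  km <- cfg$kmcm_confusion
  if (!is.matrix(km) || !identical(dim(km), c(2L, 4L)) ||
      any(km < 0) || any(abs(rowSums(km) - 1) > 1e-8)) {
    stop("`kmcm_confusion` must be a 2 x 4 matrix with rows summing to 1",
         call. = FALSE)
  }
  sg <- cfg$subgroup_probs
  if (!is.matrix(sg) || ncol(sg) != 2L || any(sg < 0) || any(sg > 1)) {
    stop("`subgroup_probs` must be a matrix of probabilities with 2 columns",
         call. = FALSE)
  }
  if (!is.finite(cfg$inter_reading_jitter) || cfg$inter_reading_jitter < 0) {
    stop("`inter_reading_jitter` must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

# Positive right-skewed interval draws with given mean (ms) and CV (percent).
# Gamma parameterised by mean/CV; CV 0 degenerates to a constant series.
draw_intervals <- function(n, mean_ms, cv_pct) {
  if (cv_pct == 0) return(rep(mean_ms, n))
  c2 <- (cv_pct / 100)^2
  shape <- 1 / c2
  stats::rgamma(n, shape = shape, rate = shape / mean_ms)
}

#' Generate one recording's pulse-interval series for a rhythm class
#'
#' Draws intervals until the recording window is filled (always at least 2).
#' `sinus` and `af` intervals are i.i.d. gamma with the configured mean and
#' CV ("irregularly irregular": AF carries no serial correlation here);
#' `sinus_with_ectopy` is a sinus base with premature-compensatory pairs
#' (0.6x, 1.4x the base mean) injected; `af_paced` is near-constant despite
#' AF ground truth. Uses the current RNG state.
#'
#' @param rhythm one of [rhythm_classes].
#' @param config a [cohort_config()].
#' @param mean_interval_ms optional participant-specific mean interval (ms);
#'   defaults to 60000 over the class mean heart rate.
#' @return numeric vector of intervals in ms.
#' @export
gen_intervals <- function(rhythm, config = cohort_config(),
                          mean_interval_ms = NULL) {
  rhythm <- match.arg(rhythm, rhythm_classes)
  validate_cohort_config(config)
  is_af <- rhythm %in% c("af", "af_paced")
  m <- mean_interval_ms %||%
    (60000 / if (is_af) config$mean_hr_af else config$mean_hr_sinus)
  cv <- switch(rhythm,
               sinus = config$sinus_cv_pct,
               sinus_with_ectopy = config$sinus_cv_pct,
               af = config$af_cv_pct,
               af_paced = config$paced_cv_pct)
  dur_ms <- 1000 * config$recording_duration_s
  n_max <- max(4L, ceiling(2 * dur_ms / m) + 4L)
  draws <- draw_intervals(n_max, m, cv)
  n <- max(2L, sum(cumsum(draws) <= dur_ms))
  out <- draws[seq_len(min(n, n_max))]
  if (rhythm == "sinus_with_ectopy" && config$ectopy_rate > 0 &&
      length(out) >= 2L) {
    out <- inject_ectopy(out, m, config$ectopy_rate)
  }
  out
}

# Premature beat + compensatory pause, mean-preserving (0.6m + 1.4m = 2m).
# At least one pair is placed so the arrhythmia flag is always earned.
inject_ectopy <- function(intervals, base_mean, rate) {
  n <- length(intervals)
  placed <- FALSE
  i <- 1L
  while (i < n) {
    if (stats::runif(1) < rate) {
      intervals[i] <- 0.6 * base_mean
      intervals[i + 1L] <- 1.4 * base_mean
      placed <- TRUE
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  if (!placed) {
    i <- sample.int(n - 1L, 1L)
    intervals[i] <- 0.6 * base_mean
    intervals[i + 1L] <- 1.4 * base_mean
  }
  intervals
}

#' Simulate the rhythm monitor's label for one participant
#'
#' The label is drawn from the class-conditional confusion distribution over
#' `normal` / `possible_af` / `unclassified` / `blank`, conditioned on ECG AF
#' status (the published confusion margins are per AF status, so the rhythm
#' class itself is not used further). Uses the current RNG state.
#'
#' @param rhythm one of [rhythm_classes] (carried for interface completeness).
#' @param ecg_af logical, ECG ground truth.
#' @param config a [cohort_config()].
#' @return one of [kmcm_labels].
#' @export
simulate_kmcm_label <- function(rhythm, ecg_af, config = cohort_config()) {
  validate_cohort_config(config)
  row <- config$kmcm_confusion[if (isTRUE(ecg_af)) "present" else "absent", ]
  sample(kmcm_labels, 1L, prob = row)
}

#' Simulate a complete synthetic screening cohort
#'
#' Each participant gets an ECG ground-truth AF status, a rhythm class,
#' arrhythmia/pacing/subgroup flags, a simulated rhythm-monitor label, and two
#' sequential pulse-interval readings (the second re-drawn from mildly
#' perturbed rhythm parameters, mimicking measurements ~95 s apart).
#' Per-participant random substreams are derived from `config$seed`, so the
#' output is reproducible and independent of evaluation order.
#'
#' @param config a [cohort_config()].
#' @return A list of class `prv_cohort` with elements `participants` (one row
#'   per participant: identity, `ecg_af`, `rhythm`, flags, `kmcm_label`),
#'   `intervals` (long format: `participant_id`, `reading_index`,
#'   `beat_index`, `interval_ms`) and the `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 50, seed = 7))
#' table(coh$participants$ecg_af)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  n <- config$n_participants
  ids <- sprintf("P%04d", seq_len(n))
  sg <- config$subgroup_probs

  part_rows <- vector("list", n)
  int_rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(participant_subseed(config$seed, i))
    af <- stats::runif(1) < config$af_prevalence
    rhythm <- if (af) {
      if (config$paced_fraction_of_af > 0 &&
          stats::runif(1) < config$paced_fraction_of_af) "af_paced" else "af"
    } else {
      if (config$ectopy_fraction > 0 && config$ectopy_rate > 0 &&
          stats::runif(1) < config$ectopy_fraction) "sinus_with_ectopy"
      else "sinus"
    }
    hr_mean <- if (af) config$mean_hr_af else config$mean_hr_sinus
    hr <- min(max(stats::rnorm(1, hr_mean, config$hr_sd_bpm), 40), 140)
    m1 <- 60000 / hr
    m2 <- m1 * max(0.5, 1 + stats::rnorm(1, 0, config$inter_reading_jitter))
    r1 <- gen_intervals(rhythm, config, m1)
    r2 <- gen_intervals(rhythm, config, m2)
    flags <- stats::runif(nrow(sg)) < sg[, if (af) 2L else 1L]
    label <- simulate_kmcm_label(rhythm, af, config)

    part_rows[[i]] <- data.frame(
      participant_id = ids[i],
      ecg_af = af,
      rhythm = rhythm,
      non_af_arrhythmia = rhythm %in% c("sinus_with_ectopy", "af_paced"),
      paced = rhythm == "af_paced",
      prior_af_diagnosis = flags[1L],
      age_ge_65 = flags[2L],
      af_risk_ge_5pct = flags[3L],
      high_chads2 = flags[4L],
      high_cha2ds2vasc = flags[5L],
      kmcm_label = label,
      stringsAsFactors = FALSE
    )
    int_rows[[i]] <- data.frame(
      participant_id = ids[i],
      reading_index = rep(c(1L, 2L), times = c(length(r1), length(r2))),
      beat_index = c(seq_along(r1), seq_along(r2)),
      interval_ms = c(r1, r2)
    )
  }
  out <- list(participants = do.call(rbind, part_rows),
              intervals = do.call(rbind, int_rows),
              config = config)
  rownames(out$participants) <- NULL
  rownames(out$intervals) <- NULL
  class(out) <- "prv_cohort"
  out
}

# Deterministic substream seed, kept below 2^31.
participant_subseed <- function(seed, i) {
  (abs(as.numeric(seed)) * 48271 + i * 65537) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prv_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf("<prv_cohort> %d participants (%d AF), %d interval rows, seed %d\n",
              nrow(p), sum(p$ecg_af), nrow(x$intervals), x$config$seed))
  invisible(x)
}
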