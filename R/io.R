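#' Read a long-format pulse-interval table
#'
#' Expected CSV schema (header required, UTF-8): `participant_id`,
#' `reading_index`, `beat_index`, `interval_ms`. Violations are reported with
#' the offending data row numbers and are fatal.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "reading_index", "beat_index", "interval_ms")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("interval file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$interval_ms)) {
    stop("interval_ms must be numeric in ", path, call. = FALSE)
  }
  bad <- which(!is.finite(df$interval_ms) | df$interval_ms <= 0)
  if (length(bad)) {
    stop("non-positive or missing interval_ms at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", " of ", path, call. = FALSE)
  }
  key <- paste(df$participant_id, df$reading_index, df$beat_index)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, reading, beat) key at row(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  df
}

#' Read a participant-level cohort table
#'
#' Required columns: `participant_id`, `ecg_af`. Recognised optional columns:
#' `rhythm`, the boolean flags (`non_af_arrhythmia`, `paced`,
#' `prior_af_diagnosis`, `age_ge_65`, `af_risk_ge_5pct`, `high_chads2`,
#' `high_cha2ds2vasc`) and `kmcm_label` (one of [kmcm_labels]; "blank" is an
#' explicit token — an empty cell is a schema error).
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("participant_id", "ecg_af"), names(df))
  if (length(miss)) {
    stop("participant file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$participant_id)) {
    stop("duplicate participant_id at row(s) ",
         paste(utils::head(which(duplicated(df$participant_id)), 5),
               collapse = ", "), " of ", path, call. = FALSE)
  }
  if (!is.logical(df$ecg_af)) {
    stop("ecg_af must be TRUE/FALSE in ", path, call. = FALSE)
  }
  if ("kmcm_label" %in% names(df)) {
    bad <- which(is.na(df$kmcm_label) | !df$kmcm_label %in% kmcm_labels)
    if (length(bad)) {
      stop("unknown or empty kmcm_label at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path,
           call. = FALSE)
    }
  }
  df
}

#' Load a cohort from its two CSV files
#'
#' @param participants_path,intervals_path paths to the participant table and
#'   the long-format interval table (see [read_participants()],
#'   [read_intervals()]).
#' @return list of class `prv_cohort` (`participants`, `intervals`,
#'   `config = NULL`).
#' @export
load_cohort <- function(participants_path, intervals_path) {
  participants <- read_participants(participants_path)
  intervals <- read_intervals(intervals_path)
  orphan <- setdiff(unique(intervals$participant_id),
                    participants$participant_id)
  if (length(orphan)) {
    stop("interval rows reference unknown participant(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  o <- order(intervals$participant_id, intervals$reading_index,
             intervals$beat_index)
  intervals <- intervals[o, , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(participants = participants, intervals = intervals,
                 config = NULL), class = "prv_cohort")
}

#' Write a cohort to a directory
#'
#' Emits `participants.csv`, `intervals.csv` and, when the cohort carries a
#' generator configuration, the resolved config as `config.json`. Every file
#' is re-readable by [load_cohort()].
#'
#' @param cohort a `prv_cohort` (from [simulate_cohort()] or [load_cohort()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "prv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(participants = file.path(dir, "participants.csv"),
             intervals = file.path(dir, "intervals.csv"))
  utils::write.csv(cohort$participants, paths["participants"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$intervals, paths["intervals"],
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    cfg$kmcm_confusion <- as.data.frame(cfg$kmcm_confusion)
    cfg$subgroup_probs <- as.data.frame(cfg$subgroup_probs)
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, config = file.path(dir, "config.json"))
  }
  invisible(paths)
}

#' Run configuration for the full screening-analysis pipeline
#'
#' @param cohort a [cohort_config()] for synthetic input, or `NULL` when
#'   loading from files.
#' @param participants_file,intervals_file CSV paths (used when `cohort` is
#'   `NULL`).
#' @param parameters PRV statistics to evaluate (non-empty subset of
#'   `sarv`, `rmssd`, `sd`, `cv`, `relative_range`, `ipp`).
#' @param rules combination rules to report (see [classify_combined()]).
#' @param rule_parameter the PRV statistic the combination rules act on.
#' @param threshold classification threshold for the combination rules, in
#'   the units of `rule_parameter`.
#' @param band uncertainty band for the `banded` rule.
#' @param exclusion_fraction,ipp_fraction beat-filter settings (see
#'   [filter_beats()], [ipp()]).
#' @param pt_grid decision-curve threshold probabilities.
#' @param prevalence_adjust prevalence for the reweighted precision-recall
#'   curve (default 0.10).
#' @param cv_folds,cv_reps repeated cross-validation settings.
#' @param seed master seed; every stochastic stage derives from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       participants_file = NULL, intervals_file = NULL,
                       parameters = c("sarv", "rmssd", "sd", "cv",
                                      "relative_range", "ipp"),
                       rules = c("first_only", "mean_of_two", "both_exceed"),
                       rule_parameter = "sarv",
                       threshold = 6,
                       band = c(6, 14),
                       exclusion_fraction = 0.25,
                       ipp_fraction = 0.15,
                       pt_grid = seq(0.05, 0.60, by = 0.01),
                       prevalence_adjust = 0.10,
                       cv_folds = 10, cv_reps = 10,
                       seed = 1L) {
  all_params <- c("sarv", "rmssd", "sd", "cv", "relative_range", "ipp")
  if (length(parameters) == 0) {
    stop("`parameters` must name at least one PRV statistic", call. = FALSE)
  }
  if (!all(parameters %in% all_params)) {
    stop("unknown PRV parameter(s): ",
         paste(setdiff(parameters, all_params), collapse = ", "),
         call. = FALSE)
  }
  if (!all(rules %in% combination_rules)) {
    stop("unknown rule(s): ",
         paste(setdiff(rules, combination_rules), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(rule_parameter %in% all_params)
  if (is.null(cohort)) {
    if (is.null(participants_file) || is.null(intervals_file) ||
        !file.exists(participants_file) || !file.exists(intervals_file)) {
      stop("cohort files must exist when no synthetic config is given",
           call. = FALSE)
    }
  }
  structure(list(cohort = cohort,
                 participants_file = participants_file,
                 intervals_file = intervals_file,
                 parameters = parameters, rules = rules,
                 rule_parameter = rule_parameter, threshold = threshold,
                 band = band, exclusion_fraction = exclusion_fraction,
                 ipp_fraction = ipp_fraction, pt_grid = pt_grid,
                 prevalence_adjust = prevalence_adjust,
                 cv_folds = cv_folds, cv_reps = cv_reps,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from JSON or YAML
#'
#' Top-level keys map to [run_config()] arguments; a `cohort` object maps to
#' [cohort_config()] arguments.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$cohort)) {
    ccargs <- raw$cohort
    if (!is.null(ccargs$kmcm_confusion)) {
      ccargs$kmcm_confusion <- matrix(unlist(ccargs$kmcm_confusion),
                                      nrow = 2, byrow = TRUE,
                                      dimnames = list(c("absent", "present"),
                                                      kmcm_labels))
    }
    raw$cohort <- do.call(cohort_config, ccargs)
  }
  do.call(run_config, raw)
}

#' Run the full screening analysis pipeline
#'
#' Orchestrates cohort acquisition (synthetic or from files), PRV computation,
#' combination-rule classification, threshold-free evaluation (ROC/AUC,
#' repeated cross-validation, decision and precision-recall curves) and,
#' when device labels are present, the label contingency report. All
#' randomness derives from `config$seed`; a fixed seed reproduces the bundle
#' exactly.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, CSV/JSON artifacts and a
#'   run log are written there.
#' @return invisibly, a list: `cohort`, `prv` (per-reading PRV table),
#'   `rule_metrics`, `evaluation` (per-parameter ROC/CV/decision/PR),
#'   `kmcm` (report + undetected breakdown, or `NULL`), `log`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  needs_label <- any(config$rules %in% c("first_and_kmcm", "mean_and_kmcm"))

  cohort <- if (!is.null(config$cohort)) {
    cc <- config$cohort
    cc$seed <- config$seed
    simulate_cohort(cc)
  } else {
    load_cohort(config$participants_file, config$intervals_file)
  }
  parts <- cohort$participants
  has_label <- "kmcm_label" %in% names(parts)
  if (needs_label && !has_label) {
    stop("rule(s) ",
         paste(intersect(config$rules, c("first_and_kmcm", "mean_and_kmcm")),
               collapse = ", "),
         " need device labels but the cohort has none", call. = FALSE)
  }

  prv <- compute_prv_table(cohort$intervals,
                           exclusion_fraction = config$exclusion_fraction,
                           ipp_fraction = config$ipp_fraction)
  unevaluable <- unique(prv$participant_id[prv$status != "ok"])

  wide <- function(param, reading) {
    sub <- prv[prv$reading_index == reading, c("participant_id", param)]
    sub[[param]][match(parts$participant_id, sub$participant_id)]
  }
  label <- parts$ecg_af

  # combination-rule classification on the designated parameter
  r1 <- wide(config$rule_parameter, 1L)
  r2 <- if (any(prv$reading_index == 2L)) wide(config$rule_parameter, 2L)
        else NULL
  labels_vec <- if (has_label) parts$kmcm_label else NULL
  rule_metrics <- lapply(config$rules, function(rl) {
    pred <- classify_combined(r1, r2, labels_vec, rule = rl,
                              threshold = config$threshold,
                              band = config$band)
    ok <- !is.na(pred)
    ct <- list(tp = sum(pred[ok] & label[ok]),
               fp = sum(pred[ok] & !label[ok]),
               tn = sum(!pred[ok] & !label[ok]),
               fn = sum(!pred[ok] & label[ok]))
    c(list(rule = rl, n_evaluable = sum(ok), n_unevaluable = sum(!ok)),
      ct, diagnostic_metrics(ct))
  })
  names(rule_metrics) <- config$rules

  # threshold-free evaluation, per parameter, on the first reading
  evaluation <- lapply(config$parameters, function(p) {
    s1 <- wide(p, 1L)
    list(parameter = p,
         roc = roc_auc(s1, label),
         cv = repeated_cv_auc(s1, label, k = config$cv_folds,
                              reps = config$cv_reps, seed = config$seed),
         decision = decision_curve(s1, label, config$pt_grid),
         pr = precision_recall(s1, label,
                               prevalence = config$prevalence_adjust),
         roc_mean2 = if (!is.null(r2)) {
           roc_auc((wide(p, 1L) + wide(p, 2L)) / 2, label)
         })
  })
  names(evaluation) <- config$parameters

  kmcm <- if (has_label) {
    xt <- kmcm_crosstab_from_cohort(parts)
    list(crosstab = xt, report = kmcm_report(xt),
         undetected = undetected_breakdown(xt))
  }

  log <- list(seed = config$seed,
              n_participants = nrow(parts),
              n_unevaluable_recordings = sum(prv$status != "ok"),
              unevaluable_participants = unevaluable,
              decision_calibration = vapply(
                evaluation, function(e) attr(e$decision, "calibration"),
                character(1)))

  bundle <- list(cohort = cohort, prv = prv, rule_metrics = rule_metrics,
                 evaluation = evaluation, kmcm = kmcm, log = log)

  if (!is.null(out_dir)) write_bundle(bundle, config, out_dir)
  invisible(bundle)
}

# Serialise the report bundle: PRV CSV, metric JSON, curve CSVs, device
# report, run log.
write_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(bundle$cohort, out_dir)
  utils::write.csv(bundle$prv, file.path(out_dir, "prv.csv"),
                   row.names = FALSE, quote = FALSE)
  metrics <- list(
    rules = bundle$rule_metrics,
    auc = lapply(bundle$evaluation, function(e) {
      list(auc = e$roc$auc, ci = unname(e$roc$ci),
           cv_mean_auc = e$cv$mean_auc,
           cv_interval = unname(e$cv$interval),
           pr_area = e$pr$area, pr_area_adj = e$pr$area_adj,
           auc_mean2 = if (!is.null(e$roc_mean2)) e$roc_mean2$auc)
    })
  )
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (p in names(bundle$evaluation)) {
    e <- bundle$evaluation[[p]]
    utils::write.csv(e$roc$curve,
                     file.path(out_dir, paste0("roc_", p, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(e$decision),
                     file.path(out_dir, paste0("decision_", p, ".csv")),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(e$pr$curve,
                     file.path(out_dir, paste0("pr_", p, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(bundle$kmcm)) {
    utils::write.csv(bundle$kmcm$report,
                     file.path(out_dir, "kmcm_report.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(bundle$kmcm$undetected,
                         file.path(out_dir, "kmcm_undetected.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
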