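# prvscreen

Opportunistic atrial fibrillation (AF) screening analysis from pulse rate
variability (PRV). AF produces irregularly irregular beat timing, so it can
be detected from the ~10–12 beat-to-beat pulse intervals recorded during an
automatic blood pressure measurement, or from a hand-held single-lead rhythm
monitor that labels a strip `normal`, `possible_af`, `unclassified` or
`blank`. This package is for biostatisticians and screening researchers who
need the full analysis layer of such a programme, reproducibly and with an
honest treatment of unreadable recordings.

It provides:

* **Six PRV statistics** from a beat-interval series $d_1,\dots,d_n$ (ms):
  sARV $= 100\,\overline{|d_{i+1}-d_i|}/\bar d$, RMSSD
  $= \sqrt{\overline{(d_{i+1}-d_i)^2}}$, SD, CV $= 100\,\mathrm{SD}/\bar d$
  (the irregularity index), relative range
  $= 100\,(\max-\min)/\bar d$, and IPP, the percentage of beats deviating
  more than ±15% from the mean beat duration. A beat-exclusion pre-filter
  (±25–30% around the raw mean) removes ectopic beats before the first five
  are computed; IPP sees the raw series.
* **Combination classifiers**: single-threshold (strict exceedance), mean
  of two readings, both readings, fusion with a non-`normal` monitor label,
  and a banded rule that asks for confirmation only inside an uncertainty
  band (default sARV 6–14%).
* **Monitor contingency analysis**: 2×4 label-by-ECG cross-tabs collapsed
  to 2×2 under explicit *penalise-unreadable* / *exclude-unreadable*
  policies, with sensitivity/specificity/accuracy/PPV/NPV and the breakdown
  of undetected AF cases.
* **Evaluation battery**: ROC/AUC with DeLong or bootstrap 95% CIs,
  repeated stratified 10×10-fold cross-validated AUC, decision curves (net
  benefit $TP/n - (FP/n)\,p_t/(1-p_t)$), precision-recall curves with
  trapezoidal area, and prevalence-adjusted PPV.
* **A synthetic cohort generator** calibrated to a primary-care screening
  population (AF prevalence 133/421, interval CV 2.1% sinus vs 12.6% AF,
  ectopic and paced rhythms, label confusion rows), so the whole pipeline is
  testable end to end without raw recordings.

## Worked example

One recording with two ectopic-like long beats; the pre-filter absorbs them,
IPP counts them:

```r
library(prvscreen)
x <- c(812, 795, 1180, 801, 790, 808, 796, 1175, 803, 799, 805)
compute_prv(x)
#>       sarv    rmssd       sd       cv relative_range      ipp n_beats_raw n_beats_used low_beat_flag
#> 1 1.264045 11.26388 6.855655 0.855887       2.746567 18.18182          11            9         FALSE
```

Low sARV/CV (≈1.3%/0.9%) says regular underlying rhythm; IPP 18% flags the
two aberrant beats. Device-label analysis from a published-style cross-tab
(288 non-AF, 133 AF participants):

```r
xt <- kmcm_crosstab(absent = c(195, 23, 57, 13), present = c(3, 111, 15, 4))
kmcm_report(xt)[, c("policy", "n", "sensitivity_pct", "specificity_pct", "accuracy_pct")]
#>                policy   n sensitivity_pct specificity_pct accuracy_pct
#> 1 penalise_unreadable 421              83              68           73
#> 2  exclude_unreadable 332              97              89           92
```

Counting the 89 unreadable strips as errors costs 14 points of sensitivity
and 21 of specificity. Discrimination on a synthetic cohort:

```r
coh <- simulate_cohort(cohort_config(n_participants = 400, seed = 9))
prv <- compute_prv_table(coh$intervals)
first <- prv[prv$reading_index == 1, ]
first <- first[match(coh$participants$participant_id, first$participant_id), ]
roc_auc(first$sarv, coh$participants$ecg_af)
#> <roc_result> AUC 0.944 (95% CI 0.903-0.984), n = 400
repeated_cv_auc(first$sarv, coh$participants$ecg_af, seed = 9)
#> <cv_auc> mean AUC 0.943 (0.800-1.000 across 100 fold estimates)
```

The cross-validated mean tracks the single-split AUC; the wide percentile
interval is what ~40-participant folds look like.

`run_pipeline(run_config(...), out_dir = "...")` orchestrates everything
(simulate or load → PRV → rules → evaluation → monitor report) and writes a
deterministic CSV/JSON bundle; `exec/prvscreen` exposes the same stages as
shell subcommands (`simulate`, `prv`, `kmcm-table`, `evaluate`, `run`).

## Scope

The package starts at interval series: waveform acquisition and beat-onset
extraction are device-specific and out of scope, as are the vendor
internals of the rhythm monitor (only its labels are modelled) and clinical
risk-score computation (subgroups are carried as boolean flags). See
`vignettes/af-screening-methods.Rmd` for the model details, generator
assumptions and design decisions.
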