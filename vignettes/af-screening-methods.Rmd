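---
title: "Detecting atrial fibrillation from pulse rate variability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation from pulse rate variability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prvscreen)
```

## The screening problem

Atrial fibrillation (AF) is the most common sustained arrhythmia and a major
treatable cause of stroke, yet it is often first diagnosed only after a
stroke has occurred. Because AF produces *irregularly irregular* beat timing,
it can be detected opportunistically from the beat-to-beat pulse intervals
recorded during an automatic blood pressure measurement, or from a hand-held
single-lead rhythm monitor that emits one of four labels: `normal`,
`possible_af`, `unclassified`, or `blank` (no analysis produced).

`prvscreen` implements the analysis layer of such a screening programme: the
pulse rate variability (PRV) statistics, the decision rules that combine one
or two PRV readings with the monitor label, contingency analysis of the
categorical monitor output, and the threshold-free evaluation battery
(ROC/AUC, repeated cross-validation, decision curves, precision-recall).
The artifact begins at the interval series; extracting beat onsets from cuff
pressure waveforms is hardware- and vendor-specific and out of scope.

## The six PRV statistics

A recording is an ordered series of beat-to-beat intervals $d_1,\dots,d_n$
(milliseconds; roughly 10–12 beats over a ~10 s window). With
$\bar d$ the series mean:

* **sARV** (standardised average real variability):
  $100 \cdot \mathrm{mean}_i\,|d_{i+1}-d_i| \,/\, \bar d$ (percent);
* **RMSSD**: $\sqrt{\mathrm{mean}_i\,(d_{i+1}-d_i)^2}$ (ms);
* **SD**: sample standard deviation (ms);
* **CV** (irregularity index): $100\cdot\mathrm{SD}/\bar d$ (percent);
* **relative range**: $100\cdot(\max d - \min d)/\bar d$ (percent);
* **IPP** (irregular pulse percentage): the percentage of beats with
  $|d_i-\bar d| > 0.15\,\bar d$.

Two band rules with different purposes apply:

1. **Beat-exclusion pre-filter** (`filter_beats()`): beats deviating more
   than `exclusion_fraction` (default 0.25, usual operating range
   0.25–0.30) from the raw-series mean are removed before sARV, RMSSD, SD,
   CV and relative range are computed. This suppresses false positives from
   ectopic beats (a premature beat plus its compensatory pause).
2. **IPP irregularity rule**: IPP is computed on the *raw* series with the
   ±15% band — the aberrant beats are exactly what it counts.

Both bands are centred on the raw-series mean, computed once, with no
iterative re-estimation. SD uses the $n-1$ denominator, the convention in
heart-rate-variability work with short recordings. A recording with fewer
than 8 raw beats is flagged (`low_beat_flag`), the proxy for a pulse rate
below 48 beats/minute over a ~10 s window. "Insufficient beats" (fewer than
two intervals surviving the filter) is a recoverable per-recording
condition: `compute_prv_table()` records it and continues, and downstream
classification treats the recording as *unevaluable* — excluded from metric
denominators, never silently counted as negative.

```{r prv-example}
x <- c(800, 800, 800, 1200)         # one ectopic-like long beat
filter_beats(x)                      # the 1200 ms beat is excluded
compute_prv(x)                       # filtered stats 0; IPP sees the outlier
```

## Classification rules

`classify_single()` uses strict exceedance (`value > threshold`; ties are
negative — the rule is "had to exceed"). `classify_combined()` implements
the combination strategies: first reading only, mean of two readings, both
readings exceeding, fusion with the monitor label (positive only when the
label is not `normal` — `unclassified` and `blank` both count as "not
normal", since neither is a normal reading), and a **banded** rule that asks
for confirmation only when the first reading falls inside an uncertainty
band (default 6–14%, the sARV range where single-reading predictions are
least reliable). Band membership is the open interval `(lower, upper)`: a
value exactly on a band edge is treated as confident, and a degenerate band
with `lower == upper` is empty, so the banded rule reduces exactly to the
first-reading rule.

## The monitor contingency analysis

`kmcm_crosstab()` holds label counts by ECG ground truth. Unreadable output
(`unclassified` + `blank`) is handled under two explicit policies:
*penalise* (unreadable recordings are deemed incorrect: false negatives
among AF cases, false positives among non-AF) or *exclude* (dropped before
the 2×2 is formed). Excluding can only raise sensitivity and specificity,
which the test suite asserts on random cross-tabs. Report percentages are
rounded half-up to whole percents, with unrounded proportions retained.

```{r kmcm}
xt <- kmcm_crosstab(absent = c(195, 23, 57, 13), present = c(3, 111, 15, 4))
kmcm_report(xt)[, c("policy", "sensitivity_pct", "specificity_pct", "accuracy_pct")]
unlist(undetected_breakdown(xt))
```

## Evaluation battery

* **ROC/AUC** (`roc_auc()`): trapezoidal ROC, so the AUC equals the
  Mann–Whitney probability that a random positive outscores a random
  negative with ties counted ½. The 95% CI is DeLong by default, with a
  seeded percentile bootstrap as the alternative (the choice matters little
  at these sample sizes; DeLong is the standard default for paired
  diagnostic data).
* **Repeated stratified k-fold CV** (`repeated_cv_auc()`, default 10×10):
  folds are stratified by label; since the marker value itself is the score
  there is nothing to tune per fold, and the AUC is simply re-estimated on
  each held-out fold. The summary is the mean and the 2.5/97.5 percentiles
  of the fold AUCs — fold-level aggregation, which reproduces the wide
  intervals characteristic of ~40-participant folds.
* **Decision curves** (`decision_curve()`): the marker is mapped to a
  predicted probability by univariate logistic calibration; at each
  threshold probability $p_t$, net benefit is
  $TP/n - (FP/n)\,p_t/(1-p_t)$, against treat-all and treat-none
  references. Under complete separation the logistic MLE diverges, and the
  mapping falls back to the score's empirical quantile; the returned object
  flags which mapping was used.
* **Precision-recall** (`precision_recall()`): operating points over the
  achieved score values; points with no positive predictions have undefined
  precision and are dropped (counted in `n_dropped`). The area is the
  trapezoid over achieved points, anchored at recall 0 with the most
  stringent achieved precision — no interpolated-precision smoothing. A
  prevalence-reweighted curve applies `ppv_at_prevalence()` (Bayes' rule)
  pointwise, typically at 10% to represent an untargeted screening
  population.

## The synthetic cohort generator

Raw recordings from screening studies are rarely deposited, so the package
ships a generator (`simulate_cohort()`) whose defaults encode the study
conditions of a primary-care screening cohort:

* AF prevalence 133/421 ≈ 0.316;
* interval series: i.i.d. gamma draws parameterised by mean and CV —
  sinus CV 2.1%, AF CV 12.6% (the published medians), mean heart rates
  70/76 beats/min with between-participant SD 15;
* two readings per participant, the second re-drawn from a mean interval
  perturbed by 2% relative noise (readings ~95 s apart drift slightly; we
  re-draw rather than re-noise the first series);
* non-AF arrhythmia: 42/288 of non-AF participants carry ectopy, modelled
  as mean-preserving premature/compensatory pairs (0.6×, 1.4× the base
  mean) — the classic false-positive mechanism the beat filter is designed
  to absorb; 7/133 of AF participants have a paced, near-constant rhythm
  (CV ≤ 0.5%) despite AF ground truth — the classic false negative;
* monitor labels drawn from the class-conditional confusion rows
  (AF present: 3/133, 111/133, 15/133, 4/133 over
  normal/possible AF/unclassified/blank; AF absent: 195/288, 23/288,
  57/288, 13/288);
* subgroup flags (prior AF diagnosis, age ≥ 65, 5-year AF risk ≥ 5%,
  elevated CHADS₂/CHA₂DS₂-VASc) drawn with the AF-conditional published
  frequencies. The age ≥ 65 margin is only published overall (314/421), so
  both strata use it.

Randomness flows from one root seed through deterministic per-participant
substreams, so cohorts are byte-reproducible and independent of generation
order.

What the generator does **not** emulate: serial correlation within AF
interval series (real AF RR series are not exactly i.i.d.; independence is
the conservative choice and at ~11 beats only the successive-difference
statistics would notice), respiratory sinus arrhythmia, the heavy-tailed
interval distribution that drives the high published IPP medians (~50% in
AF; the gamma model yields ~25%), and any age/sex structure. Consequently a
passing separation test shows the pipeline *can* operate in the published
discrimination regime (AUC ≈ 0.9), not that real recordings would reproduce
any specific published AUC — the per-parameter real-data AUCs are not
recoverable without the raw recordings.

```{r cohort}
coh <- simulate_cohort(cohort_config(n_participants = 400, seed = 9))
prv <- compute_prv_table(coh$intervals)
first <- prv[prv$reading_index == 1, ]
first <- first[match(coh$participants$participant_id, first$participant_id), ]
roc_auc(first$cv, coh$participants$ecg_af)
```

## Numerical and design choices

* Problem sizes: the bundled checks use cohorts of up to 2 000 participants
  and oracle sweeps of 1 000 random series/cohorts — large enough for the
  binomial noise on a prevalence or an AUC to sit well inside the asserted
  bands, small enough to run comfortably on a laptop.
* Thresholds/tie-breaks: strict `>` everywhere a threshold is crossed;
  ties in scores receive ½ credit in the AUC.
* Degenerate inputs are errors, not coercions: non-positive intervals,
  single-class cohorts, empty parameter lists, probabilities outside
  \[0, 1\], and threshold probabilities outside (0, 1) all fail fast with
  located messages; undefined metrics (zero denominators) are `NA`, never 0.
* The exclusion fraction is exposed as one global configuration value over
  0.25–0.30: the optimal per-dataset choice was made on data we cannot
  recompute, and there is no published indication it was tuned per
  parameter.
* `run_pipeline()` derives every stochastic stage from the single run seed,
  and each artifact it writes is re-readable by the package's own loaders.

## Limitations

The generator's parametric simplicity is deliberate: it is a test harness
and power-study scaffold, not a physiological simulator. The contingency
analysis of the monitor reproduces published-table arithmetic exactly, but
subgroup rows that depend on unpublished joint distributions (e.g. the
arrhythmia × label cross-tab) can only be produced for cohorts where those
flags are available per participant.
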