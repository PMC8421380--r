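# Independent naive-loop oracles for the PRV statistics and pairwise AUC.
# These deliberately avoid the vectorised code paths in the package.

sarv_naive <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  100 * (s / (length(x) - 1)) / (sum(x) / length(x))
}

rmssd_naive <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + (x[i + 1] - x[i])^2
  sqrt(s / (length(x) - 1))
}

sd_naive <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  sqrt(s / (length(x) - 1))
}

cv_naive <- function(x) 100 * sd_naive(x) / (sum(x) / length(x))

relrange_naive <- function(x) {
  mx <- x[1]; mn <- x[1]
  for (xi in x) { if (xi > mx) mx <- xi; if (xi < mn) mn <- xi }
  100 * (mx - mn) / (sum(x) / length(x))
}

ipp_naive <- function(x, frac = 0.15) {
  m <- sum(x) / length(x)
  k <- 0
  for (xi in x) if (abs(xi - m) > frac * m) k <- k + 1
  100 * k / length(x)
}

# AUC by brute-force positive-negative pair counting, ties counted 1/2.
auc_pairs <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

random_series <- function(n = NULL) {
  n <- if (is.null(n)) sample(5:20, 1) else n
  stats::runif(n, min = 400, max = 1400)
}

small_cohort <- function(n = 200, seed = 11) {
  simulate_cohort(cohort_config(n_participants = n, seed = seed))
}

# first-reading PRV values aligned to the participants table
prv_first_reading <- function(cohort, prv = NULL) {
  prv <- prv %||% compute_prv_table(cohort$intervals)
  s1 <- prv[prv$reading_index == 1L, ]
  s1[match(cohort$participants$participant_id, s1$participant_id), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
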