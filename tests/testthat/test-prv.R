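test_that("beat-exclusion filter keeps only beats inside the mean-centred band", {
  out <- filter_beats(c(800, 800, 800, 1200), 0.25)
  expect_equal(as.numeric(out), c(800, 800, 800))
  expect_equal(attr(out, "n_excluded"), 1L)

  # constant series: nothing excluded
  out <- filter_beats(c(800, 800, 800), 0.25)
  expect_equal(as.numeric(out), c(800, 800, 800))

  # wider band keeps everything (mean 766.7, band 536.7--996.7)
  expect_equal(as.numeric(filter_beats(c(700, 900, 700), 0.30)),
               c(700, 900, 700))

  # order preserved
  x <- c(900, 700, 950, 720)
  expect_equal(as.numeric(filter_beats(x, 0.30)), x)
})

test_that("filtering that leaves fewer than 2 beats signals insufficient beats", {
  expect_error(filter_beats(c(100, 1000, 4000), 0.25),
               class = "prvscreen_insufficient_beats")
  expect_error(sarv(1000), class = "prvscreen_insufficient_beats")
  expect_error(ipp(numeric(0)), class = "prvscreen_insufficient_beats")
  expect_error(filter_beats(c(800, 900), 1.5), "exclusion_fraction")
  expect_error(sarv(c(800, -5)), "positive")
  expect_error(sarv(c("a", "b")), "numeric")
})

test_that("the six statistics match their hand-computed example values", {
  x <- c(700, 900, 700)
  expect_equal(sarv(x), 100 * 200 / (2300 / 3), tolerance = 1e-12)
  expect_equal(rmssd(x), 200)
  expect_equal(interval_sd(x), sqrt(40000 / 3), tolerance = 1e-12)  # 115.47
  expect_equal(interval_cv(x), 100 * sqrt(40000 / 3) / (2300 / 3),
               tolerance = 1e-12)                                   # 15.06
  expect_equal(relative_range(x), 100 * 200 / (2300 / 3), tolerance = 1e-12)

  expect_equal(ipp(c(800, 800, 800, 1000)), 25)  # mean 850, band 722.5--977.5
  expect_equal(ipp(c(600, 1000)), 100)           # mean 800, band 680--920

  const <- rep(850, 10)
  expect_equal(sarv(const), 0)
  expect_equal(rmssd(const), 0)
  expect_equal(interval_sd(const), 0)
  expect_equal(interval_cv(const), 0)
  expect_equal(relative_range(const), 0)
  expect_equal(ipp(const), 0)
})

test_that("compute_prv applies the filter to five statistics but not to IPP", {
  res <- compute_prv(c(800, 800, 800, 1200))
  # filtered series is constant, so the five filtered statistics are zero
  expect_equal(res$sarv, 0)
  expect_equal(res$rmssd, 0)
  expect_equal(res$sd, 0)
  expect_equal(res$cv, 0)
  expect_equal(res$relative_range, 0)
  # IPP sees the raw series: mean 900, band 765--1035, 1 of 4 outside
  expect_equal(res$ipp, 25)
  expect_equal(res$n_beats_raw, 4L)
  expect_equal(res$n_beats_used, 3L)

  res10 <- compute_prv(rep(850, 10))
  expect_false(res10$low_beat_flag)
  expect_true(all(unlist(res10[c("sarv", "rmssd", "sd", "cv",
                                 "relative_range", "ipp")]) == 0))
  expect_true(compute_prv(rep(850, 6))$low_beat_flag)
})

test_that("scale and permutation behaviour of the statistics", {
  set.seed(101)
  for (i in 1:50) {
    x <- random_series()
    k <- runif(1, 0.2, 5)
    expect_equal(sarv(k * x), sarv(x), tolerance = 1e-10)
    expect_equal(interval_cv(k * x), interval_cv(x), tolerance = 1e-10)
    expect_equal(relative_range(k * x), relative_range(x), tolerance = 1e-10)
    expect_equal(ipp(k * x), ipp(x))
    expect_equal(rmssd(k * x), k * rmssd(x), tolerance = 1e-10)
    expect_equal(interval_sd(k * x), k * interval_sd(x), tolerance = 1e-10)

    p <- sample(length(x))
    expect_equal(interval_sd(x[p]), interval_sd(x))
    expect_equal(interval_cv(x[p]), interval_cv(x))
    expect_equal(relative_range(x[p]), relative_range(x))
    expect_equal(ipp(x[p]), ipp(x))
  }
  # successive-difference statistics are order-sensitive
  x <- c(700, 900, 700, 900)
  y <- c(700, 700, 900, 900)  # a permutation of x
  expect_false(isTRUE(all.equal(sarv(x), sarv(y))))
  expect_false(isTRUE(all.equal(rmssd(x), rmssd(y))))
})

test_that("rmssd dominates the mean absolute successive difference", {
  set.seed(202)
  for (i in 1:100) {
    x <- random_series()
    expect_gte(100 * rmssd(x) / mean(x), sarv(x) - 1e-12)
  }
})

test_that("cohort-level PRV table recovers per-recording results and recovers from bad recordings", {
  df <- data.frame(
    participant_id = rep(c("a", "a", "b"), times = c(3, 3, 3)),
    reading_index = rep(c(1L, 2L, 1L), times = c(3, 3, 3)),
    beat_index = rep(1:3, 3),
    interval_ms = c(700, 900, 700, 800, 800, 800, 100, 1000, 4000)
  )
  tab <- compute_prv_table(df)
  expect_equal(nrow(tab), 3L)
  a1 <- tab[tab$participant_id == "a" & tab$reading_index == 1L, ]
  expect_equal(a1$sarv, sarv(c(700, 900, 700)))
  expect_equal(a1$status, "ok")
  # participant b's recording collapses under the exclusion filter
  b1 <- tab[tab$participant_id == "b", ]
  expect_equal(b1$status, "insufficient_beats")
  expect_true(is.na(b1$sarv))
  # shuffled beat order is restored from beat_index
  tab2 <- compute_prv_table(df[sample(nrow(df)), ])
  expect_equal(tab2[order(tab2$participant_id, tab2$reading_index), ],
               tab[order(tab$participant_id, tab$reading_index), ],
               ignore_attr = TRUE)
})
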