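test_that("regress_eyes imputes from the cross-eye fit and never invents data", {
  # identical complete eyes: unchanged, slope 1, intercept 0
  x <- c(3.8, 4.0, 4.1, 4.3, 4.2)
  r <- regress_eyes(x, x)
  expect_identical(r$left, x)
  expect_equal(unname(r$fit_lr), c(0, 1), tolerance = 1e-12)

  # exact relation left = 2 * right; right missing where left = 4 -> imputed 2
  left <- c(2, 4, 6, 4, 8)
  right <- c(1, 2, 3, NA, 4)
  r <- regress_eyes(left, right)
  expect_equal(r$right[4], 2, tolerance = 1e-12)
  expect_identical(r$right[-4], right[-4])  # observed values untouched

  # both eyes missing stays missing
  left[2] <- NA; right[2] <- NA
  r <- regress_eyes(left, right)
  expect_true(is.na(r$left[2]) && is.na(r$right[2]))

  # under 2 jointly valid samples: pass-through with a flag
  expect_warning(r <- regress_eyes(c(1, NA, 3), c(NA, 2, NA)))
  expect_identical(r$flag, "insufficient_overlap")
  expect_identical(r$left, c(1, NA, 3))
})

test_that("mean_pupil averages available eyes", {
  expect_equal(mean_pupil(c(4.0, NA, NA), c(4.2, 4.2, NA)),
               c(4.1, 4.2, NA))
  expect_error(mean_pupil(1:3, 1:4), class = "pw_shape_error")
})

test_that("downsample bins by available-sample means", {
  expect_equal(downsample(rep(4, 60), 6), rep(4, 10))
  expect_equal(downsample(1:6, 6), 3.5)
  expect_equal(downsample(c(NA, NA, 2, NA, NA, NA), 6), 2)
  expect_true(is.na(downsample(rep(NA_real_, 6), 6)))
  expect_length(downsample(rnorm(63), 6), 10)  # partial trailing bin dropped
})

test_that("missingness exclusion uses strict > thresholds and pooled fractions", {
  cfg <- preprocess_config()
  trials <- list(make_prepared("keep", 1, 75, 100),   # exactly 75%: kept
                 make_prepared("drop", 1, 76, 100),   # 76%: trial dropped
                 make_prepared("drop", 2, 0, 100),    # pools drop to 38%: kept
                 make_prepared("gone", 1, 80, 100),   # pooled 85%: participant
                 make_prepared("gone", 2, 90, 100))
  ex <- exclude_by_missingness(trials, cfg)
  kept_ids <- vapply(ex$kept, `[[`, character(1), "participant_id")
  expect_identical(kept_ids, c("keep", "drop"))
  expect_identical(ex$report$excluded_trials$participant_id, "drop")
  expect_equal(ex$report$excluded_trials$missing_fraction, 0.76)
  expect_identical(ex$report$excluded_participants$participant_id, "gone")
  expect_equal(ex$report$excluded_participants$missing_fraction, 0.85)

  full <- exclude_by_missingness(list(make_prepared("a", 1, 0, 100)), cfg)
  expect_length(full$kept, 1)
  expect_equal(nrow(full$report$excluded_trials), 0)
  expect_equal(nrow(full$report$excluded_participants), 0)
})

test_that("median filter despikes, shrinks at edges and preserves missingness", {
  expect_equal(median_filter(rep(2.5, 30), 11), rep(2.5, 30))
  expect_equal(median_filter(c(0, 0, 0, 0, 0, 9, 0, 0, 0, 0, 0), 11),
               rep(0, 11))
  expect_equal(median_filter(5, 11), 5)
  expect_error(median_filter(1:10, 10), class = "pw_config_error")

  x <- c(1, 2, NA, 4, 100, 6, 7)
  f <- median_filter(x, 5)
  expect_true(is.na(f[3]))
  expect_false(anyNA(f[-3]))

  # monotone input stays monotone
  for (s in 1:5) {
    set.seed(s)
    mono <- cumsum(abs(rnorm(50)))
    expect_false(is.unsorted(median_filter(mono, 11)))
  }
})

test_that("gap interpolation is linear, internal-only and non-destructive", {
  expect_equal(interpolate_gaps(c(2, NA, 4)), c(2, 3, 4))
  expect_equal(interpolate_gaps(c(NA, 5, 5)), c(NA, 5, 5))
  expect_equal(interpolate_gaps(c(1, NA, NA, NA, 5)), c(1, 2, 3, 4, 5))
  expect_warning(out <- interpolate_gaps(c(NA_real_, NA_real_)))
  expect_true(all(is.na(out)))

  set.seed(4)
  x <- rnorm(100)
  holes <- sample(2:99, 20)
  y <- x; y[holes] <- NA
  expect_identical(interpolate_gaps(y)[-holes], x[-holes])
})

test_that("baseline correction subtracts the [0.5, 1.0) s window mean", {
  cfg <- preprocess_config()
  t10 <- (0:39) / 10
  const <- rep(4, 40)
  bc <- baseline_correct(const, t10, cfg)
  expect_equal(bc$baseline_mm, 4)
  expect_equal(bc$dpd, rep(0, 40))

  x <- rep(4, 40)
  x[t10 >= 0.5 & t10 < 1.0] <- c(4.0, 4.2, 4.4, 4.2, 4.2)
  x[t10 == 3] <- 4.5
  bc <- baseline_correct(x, t10, cfg)
  expect_equal(bc$baseline_mm, 4.2)
  expect_equal(bc$dpd[t10 == 3], 0.3, tolerance = 1e-12)

  x[t10 >= 0.5 & t10 < 1.0] <- NA
  expect_error(baseline_correct(x, t10, cfg), class = "pw_no_baseline")
})

test_that("preprocess applies the stages in order and reports exclusions", {
  # participant with ~80% blinked samples disappears into the report
  set.seed(8)
  n <- 60 * 10
  good <- make_raw(rnorm(n, 4, 0.1), rnorm(n, 4, 0.1), "good")
  bad_left <- rnorm(n, 4, 0.1)
  bad_left[seq_len(round(0.8 * n))] <- NA
  bad <- make_raw(bad_left, bad_left, "bad")
  out <- preprocess(list(good = good, bad = bad))
  expect_identical(unique(out$clean$participant_id), "good")
  expect_identical(out$report$excluded_participants$participant_id, "bad")
  expect_gt(out$report$excluded_participants$missing_fraction, 0.75)

  # all-missing baseline window becomes a "no baseline" exclusion
  nb_left <- rnorm(n, 4, 0.1)
  nb_left[1:120] <- NA  # first 2 s gone, baseline window inside
  nb <- make_raw(nb_left, nb_left, "nobase")
  out2 <- preprocess(list(nb = nb))
  expect_identical(out2$report$excluded_trials$reason, "no baseline")
  expect_equal(nrow(out2$clean), 0)

  # purity: identical output on identical input; empty input is empty output
  study <- simulate_study(sim_config(trial_length_s = 6),
                          list(list(label = "g", n = 2)), seed = 1)
  expect_identical(preprocess(study), preprocess(study))
  empty <- preprocess(list())
  expect_equal(nrow(empty$clean), 0)
  expect_equal(nrow(empty$report$excluded_trials), 0)
})

test_that("every clean series has zero baseline-window mean", {
  study <- simulate_study(sim_config(trial_length_s = 20, seed = 6),
                          list(list(label = "a", n = 4)), seed = 6)
  pre <- preprocess(study)
  cfg <- preprocess_config()
  for (key in unique(pre$clean$participant_id)) {
    ser <- pre$clean[pre$clean$participant_id == key, ]
    win <- ser$time_s >= cfg$baseline_start_s & ser$time_s < cfg$baseline_end_s
    expect_lt(abs(mean(ser$dpd_mm[win], na.rm = TRUE)), 1e-9)
  }
})
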