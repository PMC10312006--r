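#' Preprocessing configuration
#'
#' Tunables of the cleaning chain. Defaults follow the standard protocol for
#' pupil-diameter-change analysis: 60 to 10 Hz downsampling, strict
#' greater-than-75% missingness exclusion at trial and participant level,
#' an 11-sample rolling median on the 10 Hz grid, and a baseline window of
#' `[0.5, 1.0)` s (the second half of the first second, after the light
#' reflex has settled).
#'
#' @param in_rate_hz raw sampling rate.
#' @param out_rate_hz analysis grid rate; must divide `in_rate_hz`.
#' @param trial_missing_max a trial is dropped iff its missing fraction
#'   (on the 10 Hz mean-pupil series, before interpolation) is strictly
#'   greater than this.
#' @param participant_missing_max a participant is dropped iff the pooled
#'   missing fraction across all their trials is strictly greater than this.
#' @param median_window rolling-median window in samples (odd).
#' @param baseline_start_s,baseline_end_s half-open baseline window
#'   `[start, end)` in seconds from trial onset.
#' @param interpolate_before_filter if `TRUE`, blink interpolation runs
#'   before the median filter (the default order is filter first).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(in_rate_hz = 60L, out_rate_hz = 10L,
                              trial_missing_max = 0.75,
                              participant_missing_max = 0.75,
                              median_window = 11L,
                              baseline_start_s = 0.5, baseline_end_s = 1.0,
                              interpolate_before_filter = FALSE) {
  stopifnot(in_rate_hz %% out_rate_hz == 0,
            median_window >= 1, median_window %% 2 == 1,
            baseline_start_s >= 0, baseline_start_s < baseline_end_s,
            trial_missing_max >= 0, trial_missing_max <= 1,
            participant_missing_max >= 0, participant_missing_max <= 1)
  structure(list(in_rate_hz = as.integer(in_rate_hz),
                 out_rate_hz = as.integer(out_rate_hz),
                 trial_missing_max = trial_missing_max,
                 participant_missing_max = participant_missing_max,
                 median_window = as.integer(median_window),
                 baseline_start_s = baseline_start_s,
                 baseline_end_s = baseline_end_s,
                 interpolate_before_filter = isTRUE(interpolate_before_filter)),
            class = "preprocess_config")
}

#' Cross-impute the two eyes by mutual regression
#'
#' Fits ordinary least squares both ways (`left ~ right` and `right ~ left`)
#' on samples where both eyes are valid, then fills samples where exactly one
#' eye is missing from the corresponding fit. Observed values are never
#' altered; samples where both eyes are missing stay missing.
#'
#' @param left,right numeric vectors (NA = missing), equal length.
#' @return A list with `left`, `right` (filled), `fit_lr`, `fit_rl`
#'   (intercept/slope pairs, `NULL` when degenerate) and `flag` (`"ok"` or
#'   `"insufficient_overlap"`, in which case inputs are returned unchanged).
#' @export
regress_eyes <- function(left, right) {
  stopifnot(length(left) == length(right))
  joint <- !is.na(left) & !is.na(right)
  if (sum(joint) < 2) {
    warning("fewer than 2 jointly valid samples; eyes returned unregressed")
    return(list(left = left, right = right, fit_lr = NULL, fit_rl = NULL,
                flag = "insufficient_overlap"))
  }
  l <- left[joint]; r <- right[joint]
  ols <- function(y, x) {
    vx <- var(x)
    if (vx == 0) c(intercept = mean(y), slope = 0)
    else {
      b <- cov(x, y) / vx
      c(intercept = mean(y) - b * mean(x), slope = b)
    }
  }
  fit_lr <- ols(l, r)  # predicts left from right
  fit_rl <- ols(r, l)  # predicts right from left
  only_r <- is.na(left) & !is.na(right)
  only_l <- !is.na(left) & is.na(right)
  left[only_r] <- fit_lr["intercept"] + fit_lr["slope"] * right[only_r]
  right[only_l] <- fit_rl["intercept"] + fit_rl["slope"] * left[only_l]
  list(left = left, right = right, fit_lr = fit_lr, fit_rl = fit_rl,
       flag = "ok")
}

#' Average the two eyes per sample
#'
#' Mean of whichever eyes are available; missing only where both are missing.
#'
#' @param left,right numeric vectors of equal length.
#' @return Numeric vector of per-sample means.
#' @export
mean_pupil <- function(left, right) {
  if (length(left) != length(right))
    stop_pw("eye series lengths differ", "pw_shape_error")
  out <- rowMeans(cbind(left, right), na.rm = TRUE)
  out[is.na(left) & is.na(right)] <- NA_real_
  out
}

#' Downsample by non-overlapping bin means
#'
#' Bins of `factor` consecutive samples; each bin's value is the mean of its
#' non-missing members and is missing only when the whole bin is missing. Bin
#' timestamps are anchored at the bin start. A trailing partial bin is
#' dropped.
#'
#' @param x numeric vector on a uniform grid.
#' @param factor integer decimation factor (e.g. 6 for 60 to 10 Hz).
#' @return Numeric vector of bin means, length `floor(length(x) / factor)`.
#' @export
downsample <- function(x, factor = 6L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  nb <- length(x) %/% factor
  if (nb == 0) return(numeric(0))
  m <- matrix(x[seq_len(nb * factor)], nrow = factor)
  out <- colMeans(m, na.rm = TRUE)
  out[colSums(!is.na(m)) == 0] <- NA_real_
  out
}

#' NA-aware centered rolling median
#'
#' Missing samples are excluded from every window's median and remain missing
#' at their own positions; at the edges the window shrinks symmetrically.
#'
#' @param x numeric vector.
#' @param window odd window width in samples.
#' @return Filtered vector, same length.
#' @export
median_filter <- function(x, window = 11L) {
  if (window %% 2 == 0) stop_pw("median filter window must be odd",
                                "pw_config_error")
  cpp_median_filter(as.numeric(x), as.integer(window))
}

#' Linearly interpolate internal gaps
#'
#' Every internal run of missing samples is bridged linearly between its
#' nearest valid neighbours; leading and trailing missing runs are kept
#' missing; observed values pass through unchanged.
#'
#' @param x numeric vector on a uniform grid.
#' @return Interpolated vector (with `attr(, "flag") = "all_missing"` and a
#'   warning when there is nothing to interpolate from).
#' @export
interpolate_gaps <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0) {
    warning("series is entirely missing; returned unchanged")
    return(structure(x, flag = "all_missing"))
  }
  if (length(obs) == 1) return(x)
  filled <- approx(x = obs, y = x[obs], xout = seq_along(x),
                   method = "linear", rule = 1)$y
  filled[obs] <- x[obs]  # exact pass-through of observed samples
  filled
}

#' Baseline-correct a trial
#'
#' Baseline = mean of non-missing samples with
#' `baseline_start_s <= t < baseline_end_s`; the whole series is shifted by
#' that scalar, yielding \eqn{\Delta}PD.
#'
#' @param x numeric pupil series (mm).
#' @param time_s time axis in seconds from trial onset.
#' @param cfg a [preprocess_config()].
#' @return A list with `dpd` (baseline-subtracted series) and `baseline_mm`.
#'   Raises a condition of class `pw_no_baseline` when the window holds no
#'   valid sample.
#' @export
baseline_correct <- function(x, time_s, cfg = preprocess_config()) {
  win <- time_s >= cfg$baseline_start_s & time_s < cfg$baseline_end_s
  vals <- x[win & !is.na(x)]
  if (length(vals) == 0)
    stop_pw("no valid sample in baseline window", "pw_no_baseline")
  baseline <- mean(vals)
  list(dpd = x - baseline, baseline_mm = baseline)
}

# One trial on the 10 Hz grid with its pre-interpolation missing fraction.
prepare_trial <- function(trial_df, cfg) {
  ts <- trial_df$timestamp_ms
  if (is.unsorted(ts, strictly = TRUE))
    stop_pw(sprintf("non-monotone timestamps in trial %s of %s",
                    trial_df$trial_id[1], trial_df$participant_id[1]),
            "pw_input_error")
  left <- trial_df$pupil_left_mm
  right <- trial_df$pupil_right_mm
  left[trial_df$validity_left == 0 | !is.finite(left) | left <= 0] <- NA_real_
  right[trial_df$validity_right == 0 | !is.finite(right) | right <= 0] <- NA_real_

  eyes <- suppressWarnings(regress_eyes(left, right))
  pupil <- mean_pupil(eyes$left, eyes$right)
  ds <- downsample(pupil, cfg$in_rate_hz %/% cfg$out_rate_hz)
  list(participant_id = trial_df$participant_id[1],
       group = trial_df$group[1],
       block_id = trial_df$trial_id[1],
       series = ds,
       time_s = (seq_along(ds) - 1) / cfg$out_rate_hz,
       n_missing = sum(is.na(ds)), n_total = length(ds),
       missing_fraction = mean(is.na(ds)))
}

#' Apply trial- and participant-level missingness exclusion
#'
#' A trial is excluded iff its missing fraction (10 Hz mean-pupil series,
#' before interpolation) exceeds `trial_missing_max` strictly; a participant
#' iff the pooled missing fraction across all their trials exceeds
#' `participant_missing_max` strictly.
#'
#' @param trials list of prepared trials (internal representation carrying
#'   `participant_id`, `missing_fraction`, `n_missing`, `n_total`).
#' @param cfg a [preprocess_config()].
#' @return `list(kept, report)` where `report` is an `exclusion_report`.
#' @export
exclude_by_missingness <- function(trials, cfg = preprocess_config()) {
  excl_trials <- data.frame(participant_id = character(0),
                            block_id = integer(0), reason = character(0),
                            missing_fraction = numeric(0),
                            stringsAsFactors = FALSE)
  excl_participants <- data.frame(participant_id = character(0),
                                  reason = character(0),
                                  missing_fraction = numeric(0),
                                  stringsAsFactors = FALSE)
  if (length(trials) == 0)
    return(list(kept = trials,
                report = exclusion_report(excl_trials, excl_participants)))

  pid <- vapply(trials, `[[`, character(1), "participant_id")
  miss <- vapply(trials, `[[`, numeric(1), "n_missing")
  tot <- vapply(trials, `[[`, numeric(1), "n_total")
  pooled <- tapply(miss, pid, sum) / tapply(tot, pid, sum)
  bad_pid <- names(pooled)[pooled > cfg$participant_missing_max]
  if (length(bad_pid) > 0)
    excl_participants <- data.frame(participant_id = bad_pid,
                                    reason = "participant_missingness",
                                    missing_fraction = as.numeric(pooled[bad_pid]),
                                    stringsAsFactors = FALSE)

  kept <- list()
  for (tr in trials) {
    if (tr$participant_id %in% bad_pid) next
    if (tr$missing_fraction > cfg$trial_missing_max) {
      excl_trials <- rbind(excl_trials,
                           data.frame(participant_id = tr$participant_id,
                                      block_id = tr$block_id,
                                      reason = "trial_missingness",
                                      missing_fraction = tr$missing_fraction,
                                      stringsAsFactors = FALSE))
    } else {
      kept[[length(kept) + 1L]] <- tr
    }
  }
  list(kept = kept, report = exclusion_report(excl_trials, excl_participants))
}

exclusion_report <- function(trials, participants) {
  structure(list(excluded_trials = trials,
                 excluded_participants = participants),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report:", nrow(x$excluded_trials), "trial(s),",
      nrow(x$excluded_participants), "participant(s) excluded\n")
  if (nrow(x$excluded_trials)) print(x$excluded_trials)
  if (nrow(x$excluded_participants)) print(x$excluded_participants)
  invisible(x)
}

#' Preprocess raw recordings into clean \eqn{\Delta}PD timecourses
#'
#' Runs the full cleaning chain in fixed order: eye-to-eye regression
#' imputation, binocular averaging, 60 to 10 Hz downsampling,
#' missingness-based trial/participant exclusion, rolling-median despiking,
#' linear blink interpolation, and baseline subtraction. Per-trial failures
#' (e.g. an empty baseline window) become exclusion-report rows rather than
#' errors.
#'
#' @param recordings a list of `raw_recording` data frames (as returned by
#'   [simulate_study()] or [read_raw_tsv()]) or one combined data frame.
#' @param cfg a [preprocess_config()].
#' @return A list with `clean` (tidy data frame: `participant_id`, `group`,
#'   `block_id`, `time_s`, `dpd_mm`, `baseline_mm`) and `report` (an
#'   `exclusion_report`).
#' @export
preprocess <- function(recordings, cfg = preprocess_config()) {
  if (is.data.frame(recordings))
    recordings <- split(recordings, recordings$participant_id)
  empty_clean <- data.frame(participant_id = character(0), group = character(0),
                            block_id = integer(0), time_s = numeric(0),
                            dpd_mm = numeric(0), baseline_mm = numeric(0),
                            stringsAsFactors = FALSE)
  if (length(recordings) == 0)
    return(list(clean = empty_clean,
                report = exclusion_report(
                  data.frame(participant_id = character(0), block_id = integer(0),
                             reason = character(0), missing_fraction = numeric(0),
                             stringsAsFactors = FALSE),
                  data.frame(participant_id = character(0), reason = character(0),
                             missing_fraction = numeric(0),
                             stringsAsFactors = FALSE))))

  trials <- list()
  for (rec in recordings) {
    for (tr in split(rec, rec$trial_id))
      trials[[length(trials) + 1L]] <- prepare_trial(tr, cfg)
  }

  ex <- exclude_by_missingness(trials, cfg)
  report <- ex$report

  pieces <- list()
  for (tr in ex$kept) {
    x <- tr$series
    if (cfg$interpolate_before_filter) {
      x <- suppressWarnings(interpolate_gaps(x))
      x <- median_filter(x, cfg$median_window)
    } else {
      x <- median_filter(x, cfg$median_window)
      x <- suppressWarnings(interpolate_gaps(x))
    }
    bc <- tryCatch(baseline_correct(x, tr$time_s, cfg),
                   pw_no_baseline = function(e) NULL)
    if (is.null(bc)) {
      report$excluded_trials <- rbind(
        report$excluded_trials,
        data.frame(participant_id = tr$participant_id, block_id = tr$block_id,
                   reason = "no baseline",
                   missing_fraction = tr$missing_fraction,
                   stringsAsFactors = FALSE))
      next
    }
    pieces[[length(pieces) + 1L]] <-
      data.frame(participant_id = tr$participant_id, group = tr$group,
                 block_id = tr$block_id, time_s = tr$time_s,
                 dpd_mm = as.numeric(bc$dpd), baseline_mm = bc$baseline_mm,
                 stringsAsFactors = FALSE)
  }
  clean <- if (length(pieces)) do.call(rbind, pieces) else empty_clean
  rownames(clean) <- NULL
  list(clean = clean, report = report)
}
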