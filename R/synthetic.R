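#' Simulation configuration for synthetic dyad recordings
#'
#' Describes the statistical world the generator emulates: binocular pupil
#' traces sampled at `rate_hz` for up to `trial_length_s` seconds, made of a
#' slow tonic drift (Gaussian AR(1) generated on the `tonic_rate_hz` grid and
#' sample-and-held up to `rate_hz`, so the downsampled series has lag-1
#' autocorrelation `phi` by construction), a pupillary light-reflex transient
#' `-light_reflex_amp_mm * exp(-t / light_reflex_tau_s)` at stimulus onset,
#' correlated per-eye white measurement noise, and binocular blink gaps with
#' Poisson arrivals and exponential durations during which both eyes are
#' invalid.
#'
#' Defaults describe a realistic recording regime for a seated image-viewing
#' task: 60 s trials at 60 Hz, strong tonic autocorrelation (`phi = 0.9` on
#' the 10 Hz grid), a mean absolute diameter of 4 mm with 0.3 mm tonic and
#' 0.05 mm measurement noise, ~0.2 blinks/s of ~150 ms.
#'
#' @param n_per_group default number of participants per group when a study
#'   layout does not say otherwise.
#' @param n_trials trials (experimental blocks) per participant.
#' @param trial_length_s trial duration in seconds.
#' @param rate_hz raw sampling rate (samples/s); must be a multiple of
#'   `tonic_rate_hz`.
#' @param tonic_rate_hz grid on which the tonic AR(1) process lives (the
#'   analysis grid).
#' @param phi lag-1 autocorrelation of the tonic process on the
#'   `tonic_rate_hz` grid, in `[0, 1)`.
#' @param tonic_sd marginal SD of the tonic process (mm).
#' @param noise_sd SD of per-eye white measurement noise (mm).
#' @param eye_corr correlation of left/right measurement noise, in `[0, 1]`.
#' @param blink_rate_hz blink arrivals per second (Poisson).
#' @param blink_dur_ms mean blink duration (exponential), milliseconds.
#' @param light_reflex_amp_mm amplitude of the onset constriction transient.
#' @param light_reflex_tau_s recovery time constant of the transient.
#' @param baseline_mm mean absolute pupil diameter (mm).
#' @param seed default seed used when a caller does not supply one.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(trial_length_s = 10, seed = 1)
#' rec <- simulate_trial(cfg, seed = 1)
#' head(rec)
sim_config <- function(n_per_group = 12L, n_trials = 1L, trial_length_s = 60,
                       rate_hz = 60L, tonic_rate_hz = 10L, phi = 0.9,
                       tonic_sd = 0.3, noise_sd = 0.05, eye_corr = 0.8,
                       blink_rate_hz = 0.2, blink_dur_ms = 150,
                       light_reflex_amp_mm = 0.5, light_reflex_tau_s = 0.5,
                       baseline_mm = 4.0, seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_trials = as.integer(n_trials),
              trial_length_s = trial_length_s, rate_hz = as.integer(rate_hz),
              tonic_rate_hz = as.integer(tonic_rate_hz), phi = phi,
              tonic_sd = tonic_sd, noise_sd = noise_sd, eye_corr = eye_corr,
              blink_rate_hz = blink_rate_hz, blink_dur_ms = blink_dur_ms,
              light_reflex_amp_mm = light_reflex_amp_mm,
              light_reflex_tau_s = light_reflex_tau_s,
              baseline_mm = baseline_mm, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$phi >= 0, cfg$phi < 1,
            cfg$tonic_sd >= 0, cfg$noise_sd >= 0,
            cfg$eye_corr >= 0, cfg$eye_corr <= 1,
            cfg$blink_rate_hz >= 0, cfg$blink_dur_ms > 0,
            cfg$trial_length_s > 0, cfg$n_trials >= 1,
            cfg$light_reflex_tau_s > 0)
  if (cfg$rate_hz %% cfg$tonic_rate_hz != 0)
    stop_pw("rate_hz must be a multiple of tonic_rate_hz", "pw_config_error")
  invisible(cfg)
}

#' Group-level effect specification
#'
#' An additive \eqn{\Delta}PD offset injected into every participant of one
#' group from `onset_s` onwards, linearly ramped over `ramp_s` seconds.
#' Negative magnitudes emulate a lower-arousal group. Effects must start at or
#' after the end of the baseline window (1 s), so that baseline correction is
#' never contaminated.
#'
#' @param group_label group the effect applies to.
#' @param onset_s effect onset in seconds (>= 1).
#' @param magnitude_mm additive offset in mm (negative = lower dilation).
#' @param ramp_s seconds over which the offset ramps in linearly (0 = step).
#' @param offset_s optional end of the effect, seconds (default: trial end).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(group_label, onset_s, magnitude_mm, ramp_s = 0,
                        offset_s = Inf) {
  stopifnot(is.character(group_label), length(group_label) == 1,
            ramp_s >= 0, offset_s > onset_s)
  if (onset_s < 1)
    stop_pw("effect onset must not precede the end of the baseline window (1 s)",
            "pw_config_error")
  structure(list(group_label = group_label, onset_s = onset_s,
                 magnitude_mm = magnitude_mm, ramp_s = ramp_s,
                 offset_s = offset_s),
            class = "effect_spec")
}

#' Simulate one raw trial for one participant
#'
#' @param cfg a [sim_config()].
#' @param effect an [effect_spec()] or `NULL`.
#' @param seed integer seed; identical `cfg` + `seed` gives bit-identical
#'   output.
#' @param participant_id,group_label,trial_id identifiers stamped on the rows.
#' @return A `raw_recording`: a data frame with one row per 60 Hz sample and
#'   columns `participant_id`, `group`, `trial_id`, `timestamp_ms`,
#'   `pupil_left_mm`, `pupil_right_mm`, `validity_left`, `validity_right`.
#'   Invalid samples have missing pupil values and validity 0.
#' @export
simulate_trial <- function(cfg, effect = NULL, seed = cfg$seed,
                           participant_id = "P01", group_label = "A",
                           trial_id = 1L) {
  validate_sim_config(cfg)
  set.seed(as.integer(seed))

  hold <- cfg$rate_hz %/% cfg$tonic_rate_hz
  n10 <- round(cfg$trial_length_s * cfg$tonic_rate_hz)
  n <- n10 * hold
  t_s <- (seq_len(n) - 1) / cfg$rate_hz

  # tonic AR(1), stationary init, marginal SD = tonic_sd, on the coarse grid
  z <- rnorm(n10)
  innov <- c(cfg$tonic_sd * z[1],
             cfg$tonic_sd * sqrt(1 - cfg$phi^2) * z[-1])
  tonic <- as.numeric(stats::filter(innov, cfg$phi, method = "recursive"))
  tonic60 <- rep(tonic, each = hold)

  reflex <- -cfg$light_reflex_amp_mm * exp(-t_s / cfg$light_reflex_tau_s)

  eff <- 0
  if (!is.null(effect)) {
    frac <- if (effect$ramp_s > 0) {
      pmin(1, pmax(0, (t_s - effect$onset_s) / effect$ramp_s))
    } else {
      as.numeric(t_s >= effect$onset_s)
    }
    frac[t_s >= effect$offset_s] <- 0
    eff <- effect$magnitude_mm * frac
  }

  base <- cfg$baseline_mm + tonic60 + reflex + eff

  zc <- rnorm(n); zl <- rnorm(n); zr <- rnorm(n)
  a <- sqrt(cfg$eye_corr); b <- sqrt(1 - cfg$eye_corr)
  left <- base + cfg$noise_sd * (a * zc + b * zl)
  right <- base + cfg$noise_sd * (a * zc + b * zr)

  # binocular blinks: Poisson arrivals, exponential durations
  invalid <- logical(n)
  n_blinks <- rpois(1, cfg$blink_rate_hz * cfg$trial_length_s)
  if (n_blinks > 0) {
    starts <- runif(n_blinks, 0, cfg$trial_length_s)
    durs <- rexp(n_blinks, rate = 1000 / cfg$blink_dur_ms)
    for (i in seq_len(n_blinks))
      invalid[t_s >= starts[i] & t_s < starts[i] + durs[i]] <- TRUE
  }
  left[invalid] <- NA_real_
  right[invalid] <- NA_real_

  structure(data.frame(participant_id = participant_id, group = group_label,
                       trial_id = as.integer(trial_id),
                       timestamp_ms = t_s * 1000,
                       pupil_left_mm = left, pupil_right_mm = right,
                       validity_left = as.integer(!invalid),
                       validity_right = as.integer(!invalid),
                       stringsAsFactors = FALSE),
            class = c("raw_recording", "data.frame"))
}

#' Simulate a full multi-group study
#'
#' One recording (all trials) per participant per group, with per-participant
#' seeds derived deterministically from `seed` so the study is reproducible
#' and participants are independent.
#'
#' @param cfg a [sim_config()].
#' @param groups a list of group layouts, each a list with elements `label`,
#'   `n` (participants; defaults to `cfg$n_per_group`) and optionally
#'   `effect` (an [effect_spec()] applied to that group).
#' @param seed top-level study seed.
#' @return A named list of `raw_recording` data frames, one per participant.
#' @export
#' @examples
#' cfg <- sim_config(trial_length_s = 5)
#' study <- simulate_study(cfg, list(list(label = "parent", n = 2),
#'                                   list(label = "child", n = 2)), seed = 7)
#' length(study)
simulate_study <- function(cfg, groups, seed = cfg$seed) {
  validate_sim_config(cfg)
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels))
    stop_pw("duplicate group labels in study layout", "pw_config_error")

  out <- list()
  counter <- 0L
  for (g in groups) {
    n <- g$n %||% cfg$n_per_group
    if (n == 0) next
    eff <- g$effect %||% NULL
    if (!is.null(eff) && !identical(eff$group_label, g$label))
      stop_pw(sprintf("effect labelled '%s' attached to group '%s'",
                      eff$group_label, g$label), "pw_config_error")
    for (i in seq_len(n)) {
      counter <- counter + 1L
      pid <- sprintf("%s_%02d", g$label, i)
      trials <- lapply(seq_len(cfg$n_trials), function(b) {
        simulate_trial(cfg, effect = eff,
                       seed = derive_seed(seed, "simulate",
                                          counter * 1000L + b),
                       participant_id = pid, group_label = g$label,
                       trial_id = b)
      })
      rec <- do.call(rbind, trials)
      class(rec) <- c("raw_recording", "data.frame")
      out[[pid]] <- rec
    }
  }
  out
}
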