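#' Statistics configuration for waveform comparison
#'
#' Houses the two significance levels of the run-length procedure: the
#' pointwise level `alpha_point` (default 0.1) at which each timepoint's
#' one-tailed Welch test is thresholded, and the family-wise level `alpha_fw`
#' (default 0.05) that the Monte Carlo run-length calibration controls.
#'
#' @param alpha_point pointwise significance level.
#' @param alpha_fw family-wise significance level.
#' @param tail `"A_less"` (alternative: mean A below mean B), `"A_greater"`,
#'   or `"two_sided"`. The t sign convention is `t > 0` when
#'   `mean(A) > mean(B)`.
#' @param n_sim Monte Carlo replicates for the null run-length distribution.
#' @param min_n_per_point minimum per-group sample size for a timepoint to be
#'   testable.
#' @param window_summary `"peak"` (report t/df/p/d at the max-|t| timepoint)
#'   or `"mean"` (average them over the window).
#' @param seed seed for the Monte Carlo null.
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(alpha_point = 0.1, alpha_fw = 0.05,
                         tail = c("A_less", "A_greater", "two_sided"),
                         n_sim = 10000L, min_n_per_point = 2L,
                         window_summary = c("peak", "mean"), seed = 1L) {
  tail <- match.arg(tail)
  window_summary <- match.arg(window_summary)
  stopifnot(alpha_point > 0, alpha_point < 1, alpha_fw > 0, alpha_fw < 1,
            n_sim >= 1, min_n_per_point >= 2)
  structure(list(alpha_point = alpha_point, alpha_fw = alpha_fw, tail = tail,
                 n_sim = as.integer(n_sim),
                 min_n_per_point = as.integer(min_n_per_point),
                 window_summary = window_summary, seed = as.integer(seed)),
            class = "stats_config")
}

tail_code <- function(tail) {
  switch(tail, A_less = 0L, A_greater = 1L, two_sided = 2L,
         stop_pw("unknown tail", "pw_config_error"))
}

#' Assemble one group's waveform matrix
#'
#' Pivots tidy clean timecourses into a participants-x-timepoints matrix on
#' the shared 10 Hz axis. Rows are participant-block series; series shorter
#' than the longest get a missing tail (trials may end early).
#'
#' @param clean tidy clean data frame from [preprocess()] (optionally already
#'   restricted to one group).
#' @param group_label group to extract; `NULL` takes all rows.
#' @return An object of class `group_waveforms`: a list with `group_label`,
#'   `mat` (rows named `participant.block`), and `time_s`.
#' @export
group_waveforms <- function(clean, group_label = NULL) {
  if (inherits(clean, "group_waveforms")) return(clean)
  df <- if (is.null(group_label)) clean else clean[clean$group == group_label, ]
  if (nrow(df) == 0)
    stop_pw(sprintf("no clean timecourses for group '%s'",
                    group_label %||% "<all>"), "pw_input_error")
  if (is.null(group_label)) group_label <- df$group[1]
  key <- paste(df$participant_id, df$block_id, sep = ".")
  time_s <- sort(unique(df$time_s))
  idx <- match(df$time_s, time_s)
  rows <- unique(key)
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(time_s),
                dimnames = list(rows, NULL))
  mat[cbind(match(key, rows), idx)] <- df$dpd_mm
  structure(list(group_label = group_label, mat = mat, time_s = time_s),
            class = "group_waveforms")
}

# Welch statistic and Satterthwaite df from group moments (vectorized).
welch_from_moments <- function(mA, vA, nA, mB, vB, nB) {
  a <- vA / nA
  b <- vB / nB
  se2 <- a + b
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / (a^2 / (nA - 1) + b^2 / (nB - 1))
  zero <- !is.na(se2) & se2 == 0
  if (any(zero)) {
    d <- mA[zero] - mB[zero]
    t[zero] <- ifelse(d == 0, 0, sign(d) * Inf)
    df[zero] <- (nA[zero] + nB[zero] - 2)
  }
  list(t = t, df = df)
}

one_tailed_p <- function(t, df, tail) {
  switch(tail,
         A_less = pt(t, df),
         A_greater = pt(t, df, lower.tail = FALSE),
         two_sided = 2 * pt(-abs(t), df))
}

#' Pointwise Welch t-tests along two group waveforms
#'
#' At every timepoint, compares the groups' available (non-missing) values
#' with an unequal-variance t-test and Satterthwaite degrees of freedom;
#' participants contribute wherever observed (pairwise deletion), so degrees
#' of freedom shrink as trials end early. Timepoints where either group has
#' fewer than `cfg$min_n_per_point` values are marked untestable.
#'
#' @param waveA,waveB `group_waveforms` objects (or matrices) on a common
#'   time axis; A is the first-named group of the comparison.
#' @param cfg a [stats_config()].
#' @return Data frame with one row per timepoint: `time_s`, `mean_A`,
#'   `mean_B`, `t`, `df`, `p`, `n_A`, `n_B`, `testable`.
#' @export
pointwise_welch <- function(waveA, waveB, cfg = stats_config()) {
  A <- if (inherits(waveA, "group_waveforms")) waveA$mat else as.matrix(waveA)
  B <- if (inherits(waveB, "group_waveforms")) waveB$mat else as.matrix(waveB)
  time_s <- if (inherits(waveA, "group_waveforms")) waveA$time_s
            else (seq_len(ncol(A)) - 1) / 10
  if (ncol(A) != ncol(B))
    stop_pw("group waveforms are not on a common time axis", "pw_shape_error")

  moments <- function(M) {
    n <- colSums(!is.na(M))
    s <- colSums(M, na.rm = TRUE)
    s2 <- colSums(M^2, na.rm = TRUE)
    m <- s / n
    v <- (s2 - n * m^2) / (n - 1)
    v <- pmax(v, 0)  # guard tiny negative rounding
    list(n = n, m = m, v = v)
  }
  a <- moments(A)
  b <- moments(B)
  testable <- a$n >= cfg$min_n_per_point & b$n >= cfg$min_n_per_point
  if (!any(testable))
    stop_pw("no testable timepoint (need >= min_n_per_point per group)",
            "pw_input_error")

  w <- welch_from_moments(a$m, a$v, a$n, b$m, b$v, b$n)
  p <- one_tailed_p(w$t, w$df, cfg$tail)
  w$t[!testable] <- NA_real_
  w$df[!testable] <- NA_real_
  p[!testable] <- NA_real_
  data.frame(time_s = time_s, mean_A = a$m, mean_B = b$m,
             t = w$t, df = w$df, p = p,
             n_A = as.integer(a$n), n_B = as.integer(b$n),
             testable = testable, row.names = NULL)
}

#' Cohen's d for two samples
#'
#' Standardized mean difference `(mean_A - mean_B) / s_pooled`, with the
#' pooled SD weighted by `(n - 1)` over both groups.
#'
#' @param a,b numeric vectors (NAs dropped), each with at least 2 values.
#' @return The signed effect size; `NA` with a warning when the pooled SD is
#'   zero.
#' @export
cohens_d <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_pw("cohens_d needs >= 2 values per group", "pw_input_error")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    warning("pooled SD is zero; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Estimate the lag-1 autocorrelation of waveform residuals
#'
#' For every participant, subtracts their group's pointwise mean waveform and
#' computes the lag-1 Pearson autocorrelation of the residual series over
#' pairwise-complete lagged pairs; the estimate is the across-participant
#' mean, clipped to `[0, 0.999]` (the null model is a non-negative AR(1)).
#'
#' @param waveA,waveB `group_waveforms` objects or matrices.
#' @return `phi_hat`, a scalar in `[0, 0.999]`.
#' @export
estimate_phi <- function(waveA, waveB) {
  mats <- lapply(list(waveA, waveB), function(w)
    if (inherits(w, "group_waveforms")) w$mat else as.matrix(w))
  per_participant <- function(M) {
    if (ncol(M) < 2) stop_pw("need >= 2 timepoints", "pw_input_error")
    gm <- colMeans(M, na.rm = TRUE)
    apply(M, 1, function(row) {
      r <- row - gm
      x <- r[-length(r)]
      y <- r[-1]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3) return(NA_real_)
      if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
      cor(x[ok], y[ok])
    })
  }
  rhos <- unlist(lapply(mats, per_participant))
  if (all(is.na(rhos)))
    stop_pw("autocorrelation undefined: all residual series degenerate",
            "pw_degenerate_error")
  min(max(mean(rhos, na.rm = TRUE), 0), 0.999)
}

#' Monte Carlo null distribution of the maximal significant run
#'
#' Simulates `cfg$n_sim` null studies of `n_A + n_B` independent
#' standard-Gaussian AR(1) waveforms with coefficient `phi` (stationary
#' initialization, unit marginal variance), applies the pointwise Welch test
#' with `cfg$tail`, and records the longest run of consecutive timepoints
#' with `p < cfg$alpha_point` in each replicate (0 when none).
#'
#' @param T number of timepoints.
#' @param n_A,n_B group sizes (complete data in the null).
#' @param phi AR(1) coefficient in `[0, 1)`.
#' @param cfg a [stats_config()]; `alpha_point = 1` forces every point
#'   significant, values at or below 0 none.
#' @param seed overrides the seed derived from `cfg$seed`.
#' @return Integer vector of per-replicate maximal run lengths, class
#'   `run_null_dist`, with the simulation parameters as attributes.
#' @export
null_max_run <- function(T, n_A, n_B, phi, cfg = stats_config(),
                         seed = derive_seed(cfg$seed, "null_max_run")) {
  stopifnot(T >= 1, n_A >= 2, n_B >= 2)
  alpha <- cfg$alpha_point
  if (alpha >= 1) {
    runs <- rep(as.integer(T), cfg$n_sim)
  } else if (alpha <= 0) {
    runs <- rep(0L, cfg$n_sim)
  } else {
    runs <- cpp_null_max_run(as.integer(T), as.integer(n_A), as.integer(n_B),
                             phi, cfg$n_sim, alpha, tail_code(cfg$tail),
                             as.numeric(seed))
  }
  structure(runs, class = "run_null_dist", T = T, n_A = n_A, n_B = n_B,
            phi = phi, alpha_point = alpha, tail = cfg$tail,
            n_sim = cfg$n_sim)
}

#' Exact maximal-run tail probability for independent timepoints
#'
#' `P(longest success run >= k)` in `T` independent Bernoulli(`alpha`)
#' trials, computed exactly by dynamic programming over the current trailing
#' run length. This is the phi = 0 oracle against which the Monte Carlo null
#' is validated.
#'
#' @param T number of trials.
#' @param k run length of interest (`k > T` gives 0).
#' @param alpha per-trial success probability.
#' @return Exact probability.
#' @export
exact_max_run_tail <- function(T, k, alpha) {
  stopifnot(T >= 1, k >= 1, alpha >= 0, alpha <= 1)
  if (k > T) return(0)
  # state = current trailing run length 0..k-1, plus absorbing "reached k"
  state <- c(1, numeric(k - 1))
  absorbed <- 0
  for (i in seq_len(T)) {
    grown <- state * alpha
    absorbed <- absorbed + if (k >= 2) grown[k] else grown[1]
    new_state <- numeric(k)
    new_state[1] <- sum(state) * (1 - alpha)
    if (k >= 2) new_state[2:k] <- grown[1:(k - 1)]
    state <- new_state
  }
  absorbed
}

#' Run-length threshold at the family-wise level
#'
#' The smallest run length `k` whose empirical null tail probability
#' `P(max run >= k)` is at or below `cfg$alpha_fw`.
#'
#' @param null_dist a [null_max_run()] result (or plain integer vector).
#' @param cfg a [stats_config()].
#' @param phi_hat optional estimate to record alongside the threshold.
#' @return An object of class `run_threshold`: list with `k_samples`,
#'   `k_seconds` (at 10 Hz), `phi_hat`, `null_tail`, `n_sim`.
#' @export
run_threshold <- function(null_dist, cfg = stats_config(), phi_hat = NA_real_) {
  runs <- as.integer(null_dist)
  n_sim <- length(runs)
  if (n_sim == 0) stop_pw("empty null distribution", "pw_input_error")
  if (cfg$alpha_fw < 1 / n_sim)
    stop_pw(sprintf(paste0("alpha_fw = %g is below the Monte Carlo resolution",
                           " 1/%d; increase n_sim"), cfg$alpha_fw, n_sim),
            "pw_resolution_error")
  for (k in seq_len(max(runs) + 1L)) {
    tail_p <- mean(runs >= k)
    if (tail_p <= cfg$alpha_fw) {
      if (is.na(phi_hat) && !is.null(attr(null_dist, "phi")))
        phi_hat <- attr(null_dist, "phi")
      return(structure(list(k_samples = k, k_seconds = k / 10,
                            phi_hat = phi_hat, null_tail = tail_p,
                            n_sim = n_sim),
                       class = "run_threshold"))
    }
  }
  stop_pw("no attainable run-length threshold; increase n_sim",
          "pw_resolution_error")  # unreachable with a finite sample
}

#' @export
print.run_threshold <- function(x, ...) {
  cat(sprintf(
    "Run-length threshold: k = %d samples (%.1f s), null tail %.4f (phi_hat = %s)\n",
    x$k_samples, x$k_seconds, x$null_tail,
    ifelse(is.na(x$phi_hat), "NA", sprintf("%.3f", x$phi_hat))))
  invisible(x)
}

#' Extract significance windows from a pointwise test series
#'
#' Maximal runs of consecutive testable timepoints with
#' `p < cfg$alpha_point` that reach the calibrated run length become
#' windows; untestable timepoints break runs and are never bridged. Each
#' window reports start/end seconds (first/last timepoint of the run) and
#' t, df, p, Cohen's d evaluated at the timepoint of maximum |t|
#' (`peak_time_s`); with `cfg$window_summary = "mean"` the four statistics
#' are instead averaged over the window. For one-tailed comparisons the
#' reported `t` and `cohens_d` are oriented so that positive values mean
#' evidence in the tested direction.
#'
#' @param tests data frame from [pointwise_welch()].
#' @param threshold a [run_threshold()].
#' @param waveA,waveB the group waveforms (needed for per-window Cohen's d).
#' @param cfg a [stats_config()].
#' @return Data frame of windows: `start_s`, `end_s`, `peak_time_s`, `t`,
#'   `df`, `p`, `cohens_d`, `length_samples` (possibly zero rows).
#' @export
find_windows <- function(tests, threshold, waveA, waveB,
                         cfg = stats_config()) {
  A <- if (inherits(waveA, "group_waveforms")) waveA$mat else as.matrix(waveA)
  B <- if (inherits(waveB, "group_waveforms")) waveB$mat else as.matrix(waveB)
  sig <- !is.na(tests$p) & tests$testable & tests$p < cfg$alpha_point
  orient <- if (cfg$tail == "A_less") -1 else 1

  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    peak_time_s = numeric(0), t = numeric(0), df = numeric(0),
                    p = numeric(0), cohens_d = numeric(0),
                    length_samples = integer(0))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < threshold$k_samples) next
    idx <- starts[i]:ends[i]
    peak <- idx[which.max(abs(tests$t[idx]))]
    d_at <- function(j) suppressWarnings(cohens_d(A[, j], B[, j]))
    if (cfg$window_summary == "peak") {
      stats_row <- c(t = tests$t[peak], df = tests$df[peak], p = tests$p[peak],
                     d = d_at(peak))
    } else {
      stats_row <- c(t = mean(tests$t[idx]), df = mean(tests$df[idx]),
                     p = mean(tests$p[idx]),
                     d = mean(vapply(idx, d_at, numeric(1))))
    }
    out <- rbind(out, data.frame(
      start_s = tests$time_s[starts[i]], end_s = tests$time_s[ends[i]],
      peak_time_s = tests$time_s[peak],
      t = orient * unname(stats_row["t"]), df = unname(stats_row["df"]),
      p = unname(stats_row["p"]),
      cohens_d = orient * unname(stats_row["d"]),
      length_samples = r$lengths[i]))
  }
  rownames(out) <- NULL
  out
}

#' Compare two groups' \eqn{\Delta}PD waveforms end to end
#'
#' Orchestrates the run-length procedure: estimate the residual lag-1
#' autocorrelation, simulate the AR(1) null run-length distribution at the
#' comparison's own sizes, derive the run-length threshold at the
#' family-wise level, run the pointwise Welch tests, and extract
#' significance windows. Fully reproducible from `cfg$seed`.
#'
#' @param cleanA,cleanB each a `group_waveforms`, a waveform matrix, or a
#'   tidy clean data frame holding exactly one group.
#' @param cfg a [stats_config()].
#' @return An object of class `windows_report`: list with `group_A`,
#'   `group_B`, `tail`, `phi_hat`, `threshold`, `pointwise` (per-timepoint
#'   data frame), `windows`, and `config`.
#' @export
compare_groups <- function(cleanA, cleanB, cfg = stats_config()) {
  as_waves <- function(x, fallback) {
    if (inherits(x, "group_waveforms")) x
    else if (is.data.frame(x)) group_waveforms(x)
    else structure(list(group_label = fallback, mat = as.matrix(x),
                        time_s = (seq_len(ncol(as.matrix(x))) - 1) / 10),
                   class = "group_waveforms")
  }
  wA <- as_waves(cleanA, "A")
  wB <- as_waves(cleanB, "B")
  if (ncol(wA$mat) != ncol(wB$mat)) {
    # align on the union grid: trials may end at different times per group
    time_s <- sort(unique(c(wA$time_s, wB$time_s)))
    pad <- function(w) {
      m <- matrix(NA_real_, nrow(w$mat), length(time_s))
      m[, match(w$time_s, time_s)] <- w$mat
      w$mat <- m
      w$time_s <- time_s
      w
    }
    wA <- pad(wA)
    wB <- pad(wB)
  }
  if (nrow(wA$mat) < 2 || nrow(wB$mat) < 2)
    stop_pw("each group needs >= 2 waveforms", "pw_input_error")

  phi_hat <- estimate_phi(wA, wB)
  nd <- null_max_run(ncol(wA$mat), nrow(wA$mat), nrow(wB$mat), phi_hat, cfg)
  thr <- run_threshold(nd, cfg, phi_hat = phi_hat)
  tests <- pointwise_welch(wA, wB, cfg)
  windows <- find_windows(tests, thr, wA, wB, cfg)

  structure(list(group_A = wA$group_label, group_B = wB$group_label,
                 tail = cfg$tail, phi_hat = phi_hat, threshold = thr,
                 pointwise = tests, windows = windows,
                 config = unclass(cfg)),
            class = "windows_report")
}

#' @export
print.windows_report <- function(x, ...) {
  cat(sprintf("Waveform comparison %s vs %s (tail: %s)\n",
              x$group_A, x$group_B, x$tail))
  cat(sprintf("  phi_hat = %.3f; threshold k = %d samples (%.1f s)\n",
              x$phi_hat, x$threshold$k_samples, x$threshold$k_seconds))
  if (nrow(x$windows) == 0) {
    cat("  no significance windows\n")
  } else {
    for (i in seq_len(nrow(x$windows)))
      cat(sprintf("  window %d: %.1f-%.1f s [t(%.1f) = %.2f, p = %.3g, d = %.2f]\n",
                  i, x$windows$start_s[i], x$windows$end_s[i],
                  x$windows$df[i], x$windows$t[i], x$windows$p[i],
                  x$windows$cohens_d[i]))
  }
  invisible(x)
}
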