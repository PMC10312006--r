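---
title: "pupilwave: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pupilwave: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilwave)
```

This vignette is the package's own account of its methods: what is being
modelled, which knobs matter and why they default to what they do, what the
synthetic generator does and does not emulate, and where the design was
genuinely open. Nothing here states an empirical result that the test suite
or the acceptance script does not itself compute.

## The measurement model

A binocular eye tracker samples each eye's pupil diameter (mm) at 60 Hz
while a participant views a stimulus for up to a minute. We model the
observed diameter of eye $e$ at time $t$ as

$$ y_e(t) = \mu + s(t) + r(t) + \delta(t) + \varepsilon_e(t), $$

where $\mu$ is the participant's absolute pupil size, $s(t)$ a slow tonic
drift (arousal), $r(t) = -A e^{-t/\tau}$ the pupillary light-reflex
transient triggered by stimulus onset, $\delta(t)$ a group-level treatment
effect on dilation, and $\varepsilon_e$ per-eye measurement noise,
correlated between eyes. Blinks produce gaps where both eyes are invalid.

The analysis quantity is the *pupil diameter change*
$\Delta\mathrm{PD}(t) = \bar y(t) - b$, where $\bar y$ is the cleaned
two-eye average and $b$ the mean of $\bar y$ over the baseline window
$[0.5, 1.0)$ s. Placing the window in the second half of the first second
neutralizes most of the light reflex; with the default $\tau = 0.5$ s a
residual of $\sim e^{-1}A$ to $e^{-2}A$ survives into the window, which is
realistic — empirical baselines are taken after the reflex has *mostly*
settled, not converged.

## Preprocessing chain

`preprocess()` applies, in a fixed order: eye-to-eye regression
(`regress_eyes`), averaging (`mean_pupil`), 60→10 Hz downsampling by
6-sample bin means (`downsample`), missingness exclusion
(`exclude_by_missingness`), an 11-sample rolling median
(`median_filter`), linear blink interpolation (`interpolate_gaps`), and
baseline subtraction (`baseline_correct`). Choices worth knowing:

* **Regression imputation is non-destructive.** OLS is fit both ways on
  jointly valid samples; only samples where exactly one eye is missing are
  filled, observed values are never altered, and double-missing samples
  stay missing. With fewer than 2 jointly valid samples the trial passes
  through unregressed, flagged.
* **Missing fractions are computed on the 10 Hz series, before
  interpolation** — interpolation would otherwise mask the very
  missingness the rule screens for. Both thresholds are strict
  (`> 0.75`): a trial at exactly 75 % missing is kept. The participant
  rule pools missing and total samples across *all* of a participant's
  trials, including ones the trial rule would drop.
* **The median window is 11 samples on the 10 Hz grid** (1.1 s), since
  filtering follows downsampling in the chain. The filter is NA-aware:
  missing samples stay missing and are excluded from neighbouring
  windows; at the edges the window shrinks symmetrically. A step change
  passes through an odd centred median unchanged, so injected offsets are
  not smeared.
* **Filter-then-interpolate is the default order**; whether blink
  interpolation should precede despiking is a defensible alternative, so
  it is exposed as `interpolate_before_filter` in
  [preprocess_config()]. The package default follows the
  despike-first convention.
* **Windows are half-open** (`[start, end)`), bin timestamps sit at bin
  starts, and $t = 0$ is trial onset. A trailing partial bin (input not a
  multiple of 6 samples) is dropped.

Every emitted series satisfies
$\mathrm{mean}(\Delta\mathrm{PD}\ \text{over baseline window}) = 0$ to
$10^{-9}$; this is asserted for all outputs in the acceptance tests.

## Comparing waveforms: pointwise tests plus a run-length threshold

At each 10 Hz timepoint the groups are compared with a Welch
(unequal-variance) t-test with Satterthwaite df. Welch is the right test
here because trials end when the participant stops speaking, so late
timepoints have fewer contributors per group and no variance homogeneity
can be assumed; pairwise deletion (a participant contributes wherever
observed) makes the df shrink naturally over the trial. Timepoints with
fewer than 2 values in either group are untestable and never bridge a run.

Pointwise $p < \alpha_{point}$ (default 0.1, one-tailed) is far too
liberal across ~600 correlated tests. The package therefore calibrates a
*run-length threshold*: simulate `n_sim` null studies in which every
participant's waveform is an independent standard-Gaussian AR(1) series
with coefficient $\hat\varphi$ (stationary initialization, unit marginal
variance), apply the identical pointwise test, record the longest
significant run, and take the smallest $k$ with
$\hat P(\text{max run} \ge k) \le \alpha_{FW}$ (default 0.05). Observed
runs of at least $k$ consecutive significant timepoints become
significance windows.

* $\hat\varphi$ is estimated from the data: per participant, subtract the
  group's pointwise mean waveform and compute the lag-1 Pearson
  autocorrelation of the residual over pairwise-complete lagged pairs;
  average across participants and clip to $[0, 0.999]$. Estimating from
  residuals (rather than from the t waveform) is a design choice made
  here and documented as such. Note that $\hat\varphi$ reflects the
  *post-filter* data — the rolling median makes cleaned series smoother
  than the generating tonic process, and the calibration correctly uses
  the smoothness the test will actually see.
* The threshold is recomputed for every group pair (sizes and
  $\hat\varphi$ differ), and the AR(1) null matches only the lag-1
  autocorrelation of the data, which is the run-length procedure's core
  assumption; the family-wise error this achieves is verified empirically
  (500 null studies, acceptance criterion) rather than taken on faith.
* Per window the package reports $t$, df, $p$ and Cohen's
  $d = (\bar x_A - \bar x_B)/s_{pooled}$ at the timepoint of maximum
  $|t|$ (`peak_time_s`). Reporting the peak is a convention choice — a
  window-mean alternative is available via
  `stats_config(window_summary = "mean")` — made because the peak is
  deterministic and matches how single summary statistics are usually
  attached to multi-second windows. For one-tailed comparisons the
  reported $t$ and $d$ are oriented so that positive values mean evidence
  in the tested direction; `cohens_d()` itself stays signed as
  $\bar x_A - \bar x_B$.

### Numerical engine

The null simulation is the only compute-heavy step and is written in C++:
a xoshiro256++ generator with a polar-Marsaglia normal sampler (seeded
deterministically from the pipeline seed; portable across compilers,
unlike `std::normal_distribution`), and per-timepoint significance decided
against critical t values linearly interpolated over a 2048-point grid of
the Satterthwaite df range (the df is bounded in
$[\min(n_A, n_B) - 1,\ n_A + n_B - 2]$; the interpolation error on the
critical value is below $10^{-8}$, orders of magnitude under Monte Carlo
noise). The Monte Carlo null is validated in the tests against
`exact_max_run_tail()`, an exact dynamic program for the independent
($\varphi = 0$) case — the two routes are kept strictly separate.

All randomness flows from one top-level seed through named substreams
(`derive_seed(seed, "simulate", i)`, `derive_seed(seed,
"null_max_run")`, ...), so reruns are byte-identical and stages are
independently reproducible.

## The synthetic world

`simulate_trial()` generates the model above directly. The tonic drift is
generated *on the 10 Hz analysis grid* as a Gaussian AR(1) with
coefficient `phi`, then sample-and-held to 60 Hz: this makes the
downsampled series have lag-1 autocorrelation `phi` by construction, which
is the quantity the significance calibration consumes. Blinks arrive as a
single binocular Poisson process (physiological blinks close both eyes)
with exponential durations. Effects are additive ΔPD offsets with an
optional linear ramp and must start at or after the baseline window's end,
so baselines are never contaminated.

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `trial_length_s` | 60 s | image-description trials run up to a minute |
| `rate_hz` / `tonic_rate_hz` | 60 / 10 Hz | tracker rate / analysis grid |
| `phi` | 0.9 | pupil waveforms are strongly autocorrelated at 10 Hz |
| `baseline_mm` | 4.0 mm | typical adult pupil under ~30 lux |
| `tonic_sd` | 0.3 mm | slow arousal drift of a few tenths of a mm |
| `noise_sd` | 0.05 mm | tracker-level measurement noise per eye |
| `eye_corr` | 0.8 | the eyes dilate together; noise partly shared |
| `blink_rate_hz` | 0.2 /s | ~12 blinks/min during a visual task |
| `blink_dur_ms` | 150 ms | typical blink closure |
| `light_reflex_amp_mm`, `light_reflex_tau_s` | 0.5 mm, 0.5 s | onset constriction that mostly settles within 1 s |

Absolute pupil sizes and noise magnitudes are not dictated by the analysis
(which is baseline- and variance-normalized); these values are realistic
placeholders chosen once, not fitted quantities.

In the effect-recovery acceptance test the world is calibrated so a
−0.3 mm offset lands at $|d| \approx 1.5$ *after preprocessing*:
baseline subtraction adds the baseline's own sampling variance to every
distant timepoint (roughly doubling cross-subject variance when
$\varphi^{\Delta t}$ has decayed), so `tonic_sd = 0.175` rather than
$0.3/1.5 = 0.2$; the realized $d$ is checked empirically in the test
world itself.

What the generator does **not** emulate: gaze position and saccades,
luminance coupling between stimulus and pupil, dyadic synchrony (the two
members of a dyad are simulated independently), asymmetric or monocular
blinks, tracker-specific artifact shapes (partial occlusion ramps before
blinks). A green test suite therefore establishes that the pipeline's
*statistical* behaviour is correct under its stated model — error control
on autocorrelated Gaussian waveforms, recovery of additive effects — not
that any particular hardware's artifacts are handled optimally.

## Supporting scalar analyses

`summarize_timecourses()` reduces each participant × block to its mean
ΔPD. `oneway_anova()` is the classical between-groups F;
`twoway_anova()` uses Type II sums of squares, the standard choice for
unbalanced designs when the interaction is not the focus (group sizes of
11–12 are typical here, so designs are mildly unbalanced).
`posthoc_pairwise()` runs all pairwise Welch tests with Holm adjustment —
chosen as a conservative default since no particular post hoc procedure is
canonical for this design; the adjustment method is configurable. Dyadic
interdependence (parent and child of one dyad are not independent) is
deliberately *not* modelled — the supporting analyses are plain fixed-effects
ANOVAs, and the limitation is inherited knowingly.

## Degenerate inputs and tie-breaks

* Zero pooled SD makes Cohen's d undefined (`NA` with a warning); a zero
  Welch standard error with equal means gives $t = 0$.
* `alpha_point = 1` forces every timepoint significant (max run = T);
  `alpha_point ≤ 0` forces none.
* `run_threshold()` errors when `alpha_fw < 1/n_sim` (the empirical tail
  cannot resolve the level; the message advises a larger `n_sim`).
* An all-missing series interpolates to itself with a warning; a trial
  with no valid baseline sample is excluded with reason `"no baseline"`.
* Effects attached to the wrong group label, duplicate group labels, and
  unknown configuration keys all fail fast before computation.

## Known limitations

* The AR(1) null matches only the lag-1 autocorrelation; heavier-tailed
  or non-stationary residual structure would make the threshold
  approximate. The empirical family-wise check in the acceptance suite is
  the guard.
* No correction is applied across multiple group-pair comparisons in one
  study; each comparison controls its own family-wise error.
* Exclusion bookkeeping assumes trials are identified by
  participant × trial id; re-used trial ids across sessions must be
  disambiguated upstream.
* The Tobii reader targets the common text-export column set; other
  vendor schemas need a thin adapter in front of `read_raw_tsv()`.
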