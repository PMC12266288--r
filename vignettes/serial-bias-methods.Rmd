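---
title: "Serial biases in continuous direction reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial biases in continuous direction reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialbias)
```

## The scientific problem

When people report a continuously varying feature — here, a motion
direction on the circle — their report on each trial is not independent
of history. Two history effects dominate:

* **Serial dependence**: the current report is biased *toward* (attractive)
  or *away from* (repulsive) the stimulus seen on the previous trial. The
  effect is tuned: it is strongest when the two stimuli are moderately
  similar and vanishes when they are nearly identical or maximally
  different.
* **Cardinal anisotropy**: reports are systematically distorted relative
  to the cardinal axes (0°, 90°, 180°, 270°), with direction-dependent
  precision. Left uncorrected, this distortion masquerades as serial
  structure, because the previous stimulus direction and the current
  report error become spuriously coupled through the stimulus geometry.

This package implements an analysis chain for a two-condition
repeated-measures design in which one condition adds a concurrent
color-word (Stroop) task during the retention interval, loading executive
resources. The scientific question is whether that load changes the sign
or size of the serial bias, whether per-participant biases are a stable
trait (correlated across conditions), and how the bias unfolds *within*
a trial as measured by continuous cursor trajectories.

## The density-asymmetry statistic

All serial-bias estimates are built on *toward-coded* errors. With
`delta = wrap_signed(previous_target - current_target)`, the toward-coded
error is `error * sign(delta)`: positive always means "deviated toward
the previous stimulus". The core statistic is the **density asymmetry**

```
asymmetry = 100 * (mass_toward - mass_away) / (mass_toward + mass_away)
```

With unit weights this is the signed count asymmetry
`100 (n+ - n-)/(n+ + n-)`; its endpoints are exactly +100 (every error
toward the previous stimulus) and −100 (every error away). It deliberately
ignores error *magnitudes*, making it robust to heavy-tailed report noise:

```{r}
density_asymmetry(c(1, 2, 3))$asymmetry
density_asymmetry(c(-0.5, -8, -40))$asymmetry
density_asymmetry(c(2, 3, -1))$asymmetry
```

Because the statistic is a proportion of discrete events, each
participant-level estimate carries an irreducible **counting noise** with
standard error `100 / sqrt(n_trials)` under the null — about 4.6
percentage points at 475 usable trials per condition. This floor matters
for power analysis and for generator calibration (below).

The tuning of the bias over dissimilarity (|delta|, 0–180°) is estimated
by `rolling_asymmetry()`: at each grid point the asymmetry is recomputed
with Gaussian weights of SD 20° in dissimilarity. The 20° default matches
the scale of the tuning itself (a derivative-of-Gaussian with width 45°
peaks near 32°); a much narrower kernel starves grid points of effective
trials, a much wider one averages attraction and repulsion regimes
together. Grid points whose effective n falls below 5 are flagged
unsupported and excluded from inference rather than zero-filled.

## Anisotropy correction

The anisotropy model splits directions into four 90° bins, fits a
degree-4 polynomial of the signed distance to each bin center, and models
the residual SD as a degree-2 polynomial of distance to the nearest
cardinal axis (floored at 0.5° so that an implausibly tight fit cannot
flag everything as an outlier). Trials beyond 3 local SDs are excluded
from a refit, then re-included for scoring; trials whose *corrected*
error still exceeds 3 local SDs are flagged as outliers downstream
(flagged, never deleted — trial counts are conserved through the whole
pipeline).

Two bin layouts are fitted: bins *centered on* the cardinals and bins
*centered on* the obliques. The right layout depends on the sign of the
anisotropy: repulsion away from the cardinals makes the error profile
discontinuous *at* the cardinals, so bins whose edges sit there
(oblique-centered) keep each bin's profile continuous and fittable by a
polynomial; attraction flips the discontinuities to the obliques. The
model with the higher total Gaussian log-likelihood wins, with ties going
to the cardinal-centered layout.

A note on accuracy: a degree-4 polynomial over a 90° bin spans one full
period of a `sin(4θ)` anisotropy, so roughly 7% of a smooth sinusoidal
bias survives the correction as lack-of-fit (≈0.37° of a 5° bias when
evaluated in 10° direction bins, ≈0.28° in 15° bins). This residual is
the price of the piecewise-polynomial design, which in exchange handles
discontinuous anisotropies that a global sinusoid cannot.

## Trajectory analysis

Cursor trajectories are analyzed response-locked (time 0 = response
submission) as a **bias surface** over time-to-response × dissimilarity,
per condition, on a 90 × 90 grid with Gaussian kernels of 120 ms (time)
and 20° (dissimilarity). Each observer contributes a kernel-weighted mean
surface; a cell is masked for an observer whose effective trial count
there falls below 5 (masked cells propagate to the group as NA — they
are never zero-filled, which would bias group means toward 0). The time
axis is truncated at the latest onset at which *every* observer still has
at least 20 trials long enough to cover it, so early cells are never
dominated by a few slow trials. Group inference is a per-cell one-sample
t-test (p < .05, uncorrected), and contiguous same-sign significant cells
are labelled as 4-connected clusters. No cluster-mass correction is
applied; the clusters summarize topography rather than establish
family-wise significance.

Complementary frame-level analyses ask *when* the bias arises: the sign
of the toward-coded deviation at the first recorded frame (stratified by
the trial's final bias sign), a per-participant logistic model of whether
the first-frame sign predicts the final sign (slopes capped at ±10 under
complete separation), and the fraction of attractive-ending trials whose
second frame already deviates away from the previous stimulus.

## The synthetic generator

`sim_config()` / `simulate_experiment()` produce complete experiments —
trial table, trajectory table, and the injected ground truth — from one
seed. Key parameters (defaults in parentheses):

* **Scale**: 33 participants × 5 blocks × 96 trials per condition, two
  conditions. These defaults are the study conditions for the acceptance
  analyses; tests vary them only where a criterion explicitly calls for a
  different scenario.
* **Serial bias**: derivative-of-Gaussian tuning
  `b(Δ) = a (Δ/w) exp(−(Δ/w)²)` with width `w = 45°`. Per-subject
  amplitudes are specified on the *measured* asymmetry scale in percent
  (means +1.9 / −1.61, SD 8.5, cross-condition correlation 0.7). The
  generator converts a target asymmetry to degrees via the small-signal
  linearization `a = A σ √(π/2) / (100 · mean DoG shape)` and, because a
  measured asymmetry is latent amplitude *plus* counting noise, subtracts
  the analytic counting variance `100²/n_eff` from the requested SD and
  inflates the latent correlation accordingly (capped at 1, with the
  realized values recorded in the ground truth). Without this calibration
  the simulated between-subject spread and cross-condition correlation
  would understate their requested values at any finite trial count.
* **Anisotropy and noise**: `sin(4θ)` repulsion of 5° (or a sawtooth
  variant, discontinuous at the repelled axes, for scheme-selection
  tests), plus wrapped Gaussian noise whose SD rises from 8° at the
  cardinals to 10° at the obliques.
* **Contaminants**: 2% swap trials (report centered on the previous
  target) and 1% uniform outliers.
* **Response times**: linear in dissimilarity (−0.88 ms/°), a −80 ms
  offset in the dual-task condition, per-subject random intercepts and
  slopes, floored at 200 ms.
* **Trajectories**: sampled at 60 Hz; the toward-coded path is an early
  Gaussian lobe (−4° peak, tuned to intermediate dissimilarities of
  ~80°) that decays into the final report error (`u⁴` easing), with 3°
  jitter. First-frame sign agreement with the final bias (0.61) and the
  probability that an attractive trial's second frame is repulsive (0.43)
  are controlled directly. The final sample reproduces the report
  exactly.

**Realism and limits.** The generator reproduces the statistical
structure the analyses assume — tuned serial bias with stable
per-subject amplitudes, anisotropic errors, RT–dissimilarity coupling,
early-repulsive/late-attractive trajectories — but it is not a process
model: noise is Gaussian rather than mixtures fit to data, trial-to-trial
amplitude fluctuations are absent (the per-subject amplitude is fixed),
trajectories follow a parametric easing curve rather than motor dynamics,
and the Stroop task affects only its own columns (no interference with
report noise is injected beyond the condition-specific bias means).

## Pipeline and problem sizes

`run_pipeline(pipeline_config(...))` chains ingest/simulation, anisotropy
correction, serial-bias estimation (per-subject asymmetries, paired
condition contrast with Cousineau–Morey within-subject CIs, bias curves),
the trajectory stage, Stroop congruency contrasts, and the RT model
(two-stage OLS by default; a single hierarchical lme4 fit as an option).
Trial counts in/used/excluded are asserted to be conserved at every
stage, and a fixed seed yields a byte-identical JSON report.

Default problem sizes are the package's own choices, made to keep the
full acceptance suite within a desktop budget: the full-scale recovery
study uses 100 replicates of 33 × 960 trials (~2 min), surface recovery
20 replicates of 20 × 576 trials with trajectories (~1 min), and test
calibration ≥500 null replicates per test family (~2 min). The 90 × 90
surface grid resolves the 120 ms / 20° kernels comfortably (~13 ms and
~2° per cell); halving the grid changes cluster summaries only at the
cell-quantization level.

## Known limitations

* The density asymmetry's counting floor (`100/√n`) caps attainable
  power for small mean asymmetries (±2%) at this design's trial counts;
  see the package's acceptance tests for the exact consequences.
* Pointwise (uncorrected) significance maps overstate cluster-level
  evidence; cluster summaries should be read descriptively.
* The anisotropy polynomial leaves a small systematic residual for
  smooth sinusoidal biases (above).
* The two-stage RT model treats per-participant OLS estimates as
  exchangeable draws; with very few trials per participant the lme4
  variant is preferable.
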