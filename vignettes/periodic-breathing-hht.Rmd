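---
title: "Detecting exercise-induced periodic breathing with EMD and the Hilbert transform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting exercise-induced periodic breathing with EMD and the Hilbert transform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epbhht)
```

## The problem and the model

Chronic heart failure patients undergoing cardiopulmonary exercise
testing (CPET) sometimes develop *periodic breathing* (PB): a slow
(tens of seconds) waxing and waning of minute ventilation superimposed
on the exercise ramp, associated with poor prognosis. The measurement
is one VE value (L/min) per breath, so the series is irregularly
sampled in time, nonstationary (the ramp dominates), and contaminated
by *gasping artifacts*: a single irregular exhalation that the
breath-by-breath gas-exchange computation records as two or more
spuriously low breaths.

The pipeline treats PB detection as a mode-decomposition problem:

1. restrict attention to the `k = 200` breaths before the VE maximum,
   where PB expresses most strongly;
2. remove gasping artifacts with an autoregressive filter — fit
   `ŷ_t = c + φ₁ y_{t−1} + ⋯ + φ_p y_{t−p}` (order 6) once to the raw
   window and delete every breath with `y_t < 0.8 ŷ_t`, yielding the
   "most exhausted exercise ventilations" (MEE-Ve);
3. decompose MEE-Ve by empirical mode decomposition (EMD) into
   intrinsic mode functions (IMFs) plus a monotone residue (the ramp);
4. screen each IMF against a white-noise null in the (mean period,
   energy) plane at the 95% and 99% levels;
5. summarise each IMF by its count of prominent peaks `Δᵢ` and compare
   PB vs non-PB cohorts per IMF with two-sample *t*-tests.

All analysis indexes by *breath number*, not seconds: breaths are
irregular in time, and every stage (window, AR lags, EMD, instantaneous
frequency in cycles/breath) is defined on the sample index.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 200 breaths | pre-peak window (≈ 4–6 min near peak rates) |
| `ar_order` | 6 | AR model order for the gasp filter |
| `ar_threshold` | 0.8 | removal rule `y < 0.8 ŷ` |
| `sd_stop` | 0.2 | EMD Cauchy sifting tolerance (classical 0.2–0.3) |
| `max_sift` | 50 | per-IMF sifting cap |
| `max_imfs` | 10 | decomposition cap (data-driven count; never hard-coded to 5) |
| `prominence_frac` | 0.5 | peak prominence threshold, × RMS of the IMF |
| `levels` | 0.95, 0.99 | significance screening levels |
| `n_null` | 1000 | white-noise realisations for the null curves |

`k`, the AR order and the 0.8 threshold are the constants of the
published analysis; the EMD and peak-detection constants are this
package's documented choices where the original is silent or
proprietary.

## The synthetic world

`generate_subject()` emulates a 10–15 minute incremental test:
respiratory rate ramps linearly 15 → 40 breaths/min over a 600 s
exercise phase (adult resting rates are 12–20/min, rising to 30–50/min
at load) and returns toward rest over 180 s of recovery. Breath onsets
invert the cumulative breath count `N(t) = ∫ r(s)/60 ds`, so the total
count matches the integrated rate within one breath. Clean VE ramps
10 → 60 L/min and decays exponentially in recovery (time constant one
third of the recovery phase). On top of the trend:

- **PB modulation** `1 + m·sin(2πt/T + φ)` with depth `m` drawn in
  0.2–0.5 for PB subjects (near 0 for non-PB) and period `T` in
  40–90 s. The published cohort's actual oscillation depth and period
  are not quantified anywhere we can check, so these ranges are chosen
  once to put several full PB cycles inside a 200-breath window at
  near-peak breath rates; they are configurable and *cannot be
  validated against the original data*.
- **Noise** is multiplicative lognormal (σ = 0.08 on the log scale):
  VE is positive and measurement scatter grows with level.
- **Gasps**: with probability 0.03 per breath the breath is replaced by
  *two* adjacent breaths, each drawn uniformly in [0.2, 0.6] × trend —
  always below the 0.8 × trend line, so the filter has true positives
  to find. VE magnitudes (10/60 L/min) and the gasp rate are clinically
  plausible placeholders, not published values.

A green synthetic test therefore establishes that the pipeline detects
the *stated* kind of PB in the *stated* kind of noise; it does not
establish performance on real CPET recordings, whose artifact structure
(mask leaks, talking, swallowing) is richer.

## Numerical choices

- **AR fitting** minimises one-step squared error by least squares on
  the lag matrix with intercept, solved via SVD with minimum-norm
  coefficients. On full-rank inputs this *is* ordinary least squares;
  on the numerically collinear windows produced by smooth noise-free
  ramps the coefficient vector is not identifiable but the predictions
  (the only quantity the filter uses) are the unique projection, so the
  filter remains well defined. Truly constant windows raise a
  degenerate-series error. Predictions are one-step-ahead from
  *observed* predecessors — the removal rule compares each measured
  breath against what its own measured history predicts.
- **Filtering is single-pass**: fit once on the raw window, predict
  once, remove. No refit, no iteration. A consequence worth knowing:
  when a gasp event's two low breaths are adjacent, the second one is
  predicted from the first (observed, low) breath, so it can escape the
  threshold when lag-1 weight dominates. At the event level every
  artifact is caught (its first breath always falls below threshold);
  at the breath level recall is ≈ 70–90%. Likewise a strong PB
  oscillation plus noise costs precision: the linear predictor
  overshoots on oscillation descents. We keep the single-pass
  observed-lag semantics because the removal rule's reference example
  fixes them, and we report both recall notions in the acceptance
  script rather than silently switching to a sequential or
  replace-and-predict variant.
- **EMD sifting** stops when the Cauchy criterion
  `Σ(h_{k−1}−h_k)²/Σh_{k−1}² < 0.2` *and* the component is well formed
  (extrema and zero-crossing counts differ by ≤ 1), capped at 50
  sifts. The Cauchy rule alone demonstrably stops on components still
  carrying riding waves; the well-formedness companion is the classical
  remedy and costs nothing measurable in reconstruction error
  (≤ 1e−15 relative, telescoping by construction).
- **Envelopes** are natural cubic splines through the extrema, with the
  two nearest extrema mirrored across each end to suppress boundary
  swings; plateaus contribute their first sample; endpoints are never
  extrema. If one side has fewer than two extrema the component is
  finalised as is.
- **Instantaneous frequency** is the forward first difference of the
  unwrapped analytic-signal phase, no smoothing, in cycles per breath.
- **Significance curves**: IMF summaries of `n_null` unit-variance
  white-noise series are binned in log mean period (20 equal bins);
  per-bin upper quantiles are interpolated linearly and forced
  non-increasing in log period by a right-to-left running maximum —
  the theoretical white-noise energy–period relation is decreasing, and
  sparse long-period bins otherwise jitter. The input series is
  rescaled to unit variance before comparison, which also makes flags
  exactly scale-invariant. A Monte-Carlo null was chosen over
  closed-form spread curves as self-contained and directly testable;
  measured false-flag rate at the 95% level is ≈ 4% per (IMF,
  replicate) pair.
- **Peak counting** replaces the original proprietary peak-fitting
  routine with prominence-thresholded local maxima: count interior
  maxima with positive value and topographic prominence
  ≥ 0.5 × RMS. This is documented, exactly reproducible, and verified
  against an exhaustive scan oracle — but its integer counts on real
  data may differ from the published per-subject table by small
  amounts; the group-level *t*-test conclusions on that table are the
  reproducible surface.
- **Mean period** of an IMF is `N / (number of interior maxima)`
  (period `N` when no peaks), consistent with the peak-count feature.
- **t-tests** are pooled-variance Student by default (the classical
  reading), Welch behind a flag; both satisfy the published bounds on
  the reference table. Zero variance in both groups with equal means
  yields t = 0, p = 1. No multiple-testing correction, matching the
  original analysis.

## Open choices decided here

- The original work does not state whether the AR fit precedes or
  follows removal, or whether filtering iterates; single-pass
  fit-then-filter is assumed (and its consequences documented above).
- Whether the 200-breath window includes the peak breath is ambiguous;
  it is excluded ("before the largest ventilation volume"), ties on
  the maximum resolve to the first occurrence.
- The published significance figure and its caption disagree on
  whether the slowest IMF fails the 99% or the 95% limit; the package
  reports flags at both levels and takes no side.
- Whether the published group *p*-values used all 61 subjects or the 20
  printed ones is unknown; this package asserts only the printed
  bounds, which hold for the printed 20 (pooled p ≈ 0.51, 0.52, 0.010,
  0.011 for Δ₁…Δ₄).
- The config file format is a minimal `key: value` text dialect
  (comma-separated vectors) parsed in-package, avoiding any YAML
  dependency.

## Known limitations

- Exact numeric replication of the original figures is not promised:
  the original EMD's stopping rule, boundary handling and spline type
  are unpublished, as is the peak detector's parameterisation.
- The gasp filter's breath-level recall and precision are bounded by
  its single-pass observed-lag design (see above); a robust or
  iterative variant is deliberately out of scope.
- The white-noise null ignores serial correlation; a red-noise null is
  out of scope.
- The synthetic generator does not model gas exchange (VO₂/VCO₂),
  tidal-volume/rate partitioning, or fitting to the original public
  data.
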