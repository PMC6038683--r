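# epbhht

Quantitative detection of **exercise-induced periodic breathing (PB)**
from breath-by-breath ventilation recorded during cardiopulmonary
exercise testing (CPET).

PB — oscillatory hyperventilation alternating with hypopneas near peak
exertion — is a poor-prognosis marker in chronic heart failure. CPET
systems measure minute ventilation (VE, L/min) once per breath, but the
raw series is contaminated by gasping artifacts (one irregular
exhalation recorded as two or more spuriously low breaths) and
dominated by the exercise ramp. This package implements a fully
reproducible pipeline for clinicians and signal-processing researchers:

1. **Windowing** — keep the `k = 200` breaths before the global VE
   maximum, where PB is most pronounced.
2. **MEE-Ve filtering** — fit an AR(6) model
   `ŷ_t = c + φ₁ y_{t−1} + … + φ₆ y_{t−6}` to the window by least
   squares and discard every breath with `y_t < 0.8 ŷ_t` (the gasping
   signature). The surviving series is the *most exhausted exercise
   ventilations* (MEE-Ve).
3. **Empirical mode decomposition** — sift the MEE-Ve signal into
   intrinsic mode functions (IMFs) `C₁ … C_n` plus a monotone residue,
   `X(t) = Σⱼ Cⱼ(t) + r(t)`, ordered fast to slow; per-IMF amplitude,
   phase and instantaneous frequency come from the Hilbert analytic
   signal (units: cycles per breath, since breaths are irregular in
   time).
4. **White-noise screening** — each IMF's (mean period `T̄ⱼ`, energy
   `Eⱼ = mean(Cⱼ²)`) pair is compared against Monte-Carlo 95%/99%
   confidence curves from unit-variance Gaussian noise (energy–period
   null, `log E ≈ −log T̄ + const`).
5. **Features and group comparison** — the number of prominent peaks in
   each IMF (`Δᵢ`, prominence ≥ 0.5 × RMS) summarises its oscillatory
   pattern; PB vs non-PB cohorts are compared per IMF with two-sample
   Student's *t*-tests (pooled by default, Welch optional).

A synthetic CPET generator (`generate_subject()`, `generate_cohort()`)
produces labeled PB / non-PB recordings — ramping breath rate
(15 → 40 breaths/min) and VE (10 → 60 L/min), sinusoidal PB modulation,
multiplicative lognormal noise, paired gasp artifacts — so the whole
pipeline is testable without clinical data.

## Worked example

```r
library(epbhht)

s <- generate_subject(subject_params(pb_amplitude = 0.4, pb_period = 60,
                                     seed = 7), subject_id = "pb0007")
s
#> <breath_series> pb0007 [PB], 367 breaths, 4.0-778.0 s, VE 3.90-91.07 L/min

res <- run_subject(s, pipeline_config(n_null = 500, seed = 1))
res$meeve
#> <meeve_result> window [52, 251], AR(6), threshold 0.80: kept 187, removed 13
res$significance
#> <significance_result>
#>  index mean_period    energy log_period log_energy sig0.95 sig0.99
#>      1    2.968254 0.1604139   1.087974 -1.8299981   FALSE   FALSE
#>      2   10.388889 0.3631670   2.340737 -1.0128926    TRUE   FALSE
#>      3   37.400000 0.8210225   3.621671 -0.1972048    TRUE    TRUE
res$features$deltas
#> delta1 delta2 delta3
#>     41     12      5
```

The injected 60-s PB cycle appears as IMF 3 (mean period 37 breaths at
the near-peak breath rate) and is the only component significant at the
99% level; IMF 1 is measurement noise and indistinguishable from the
white-noise null.

Comparing the peak-count features of the 20 published reference
subjects (10 PB, 10 non-PB, `published_peak_counts()`):

```r
compare_cohorts(features_from_table(published_peak_counts()))
#>   imf_index mean_pb mean_npb      t      p
#> 1         1     7.9      6.2  0.667 0.5132
#> 2         2    26.8     27.5 -0.651 0.5234
#> 3         3    13.5     15.8 -2.863 0.0103
#> 4         4     6.0      7.6 -2.848 0.0107
#> 5         5     2.5      3.4 -2.377 0.0287
```

Δ₃ and Δ₄ separate the groups (p < 0.02) while Δ₁ and Δ₂ do not
(p > 0.1): non-PB patients show *more* mid-frequency oscillation peaks,
PB patients fewer, slower swings.

## Command line

```sh
Rscript inst/cli/epbhht.R simulate --n-pb 10 --n-npb 10 --seed 1 --outdir sim
Rscript inst/cli/epbhht.R filter --input sim/pb0001.csv --output mee.csv
Rscript inst/cli/epbhht.R decompose --input mee.csv --output imfs.csv
Rscript inst/cli/epbhht.R significance --input imfs.csv --n-null 500 --seed 1
Rscript inst/cli/epbhht.R run-all --n-pb 10 --n-npb 10 --seed 1 --outdir out
```

## Package layout

- `R/synthetic.R` — synthetic CPET ventilation generator
- `R/io.R` — breath-series and cohort-manifest CSV dialects
- `R/meeve.R` — pre-peak window, AR fitting, gasp filter
- `R/emd.R` — EMD sifting, Hilbert analytic signal
- `R/significance.R` — Monte-Carlo white-noise IMF screening
- `R/features.R` — prominence peak counts, *t*-tests, cohort comparison
- `R/pipeline.R`, `R/cli.R` — orchestration, config files, CLI
- `vignettes/periodic-breathing-hht.Rmd` — methods notes: model,
  assumptions, numerical choices, known limitations
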