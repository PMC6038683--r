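Package: epbhht
Title: Detection of Exercise-Induced Periodic Breathing from
    Breath-by-Breath Ventilation via the Hilbert-Huang Transform
Version: 0.1.0
Authors@R:
    person("EPB", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of exercise-induced periodic breathing
    (PB) in cardiopulmonary exercise testing (CPET). Breath-by-breath
    minute-ventilation series are windowed to the 200 breaths preceding
    peak ventilation, cleaned of gasping artifacts with an autoregressive
    AR(6) outlier filter (the "most exhausted exercise ventilations",
    MEE-Ve), decomposed into intrinsic mode functions by empirical mode
    decomposition, screened against a Monte-Carlo white-noise null
    (energy-density versus mean-period), and summarised per subject by
    the number of oscillation peaks in each IMF.  Per-IMF peak counts are
    compared between PB and non-PB cohorts with two-sample t-tests.
    Includes a synthetic CPET ventilation generator for end-to-end
    testing without clinical data, CSV input/output for breath series and
    cohort manifests, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
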