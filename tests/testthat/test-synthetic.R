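test_that("parameter validation names the offending field", {
  expect_error(subject_params(rest_rate = 50, peak_rate = 40),
               "peak_rate")
  expect_error(subject_params(ve_rest = 70), "ve_peak")
  expect_error(subject_params(pb_amplitude = 1.2), "pb_amplitude")
  expect_error(subject_params(gasp_prob = 1), "gasp_prob")
  expect_error(subject_params(pb_period = -3), "pb_period")
})

test_that("noise-free, modulation-free series equals the clean trend", {
  s <- generate_subject(subject_params(pb_amplitude = 0,
                                       noise_sigma = 0, gasp_prob = 0))
  expect_equal(s$ve, attr(s, "clean_trend"))
  # single global maximum at the end of the exercise phase
  i_max <- which.max(s$ve)
  expect_equal(sum(s$ve == max(s$ve)), 1L)
  expect_equal(s$times[i_max],
               subject_params()$exercise_duration, tolerance = 0.05)
})

test_that("breath count matches the integrated breath rate within 1", {
  for (seed in c(1L, 7L)) {
    p <- subject_params(gasp_prob = 0, seed = seed)
    s <- generate_subject(p)
    r <- function(t) {
      ifelse(t <= p$exercise_duration,
             p$rest_rate + (p$peak_rate - p$rest_rate) *
               t / p$exercise_duration,
             p$peak_rate - (p$peak_rate - p$rest_rate) *
               pmin(1, (t - p$exercise_duration) / p$recovery_duration))
    }
    expected <- stats::integrate(function(t) r(t) / 60, 0,
                                 p$exercise_duration +
                                   p$recovery_duration)$value
    expect_lte(abs(length(s) - expected), 1)
  }
})

test_that("PB modulation appears at the configured frequency (FFT oracle)", {
  p <- subject_params(pb_amplitude = 0.4, pb_period = 60,
                      noise_sigma = 0, gasp_prob = 0, seed = 3)
  s <- generate_subject(p)
  detrended <- s$ve / attr(s, "clean_trend") - 1
  grid <- seq(min(s$times), max(s$times), by = 1)  # resample to 1 Hz
  z <- stats::approx(s$times, detrended, xout = grid)$y
  spec <- Mod(stats::fft(z - mean(z)))[2:(length(z) %/% 2)]
  f_peak <- which.max(spec) / length(z)
  expect_lte(abs(f_peak - 1 / 60), 1 / length(z))  # within one bin
  # and the detrended series is a pure sinusoid of depth m
  expect_equal(max(abs(detrended)), 0.4, tolerance = 1e-3)
})

test_that("gasp artifacts are pairs of low breaths below 0.8 x trend", {
  s <- generate_subject(subject_params(gasp_prob = 0.1, seed = 11))
  g <- attr(s, "gasp_indices")
  expect_gt(length(g), 0)
  expect_true(all(s$ve[g] < 0.8 * attr(s, "clean_trend")[g]))
  expect_true(all(s$ve[g] >= 0.2 * attr(s, "clean_trend")[g] - 1e-9))
  # artifacts come in adjacent pairs
  runs <- split(g, cumsum(c(1, diff(g) != 1)))
  expect_true(all(lengths(runs) %% 2 == 0))
})

test_that("generation is deterministic for a fixed seed", {
  p <- subject_params(pb_amplitude = 0.3, seed = 42)
  expect_identical(generate_subject(p), generate_subject(p))
  c1 <- generate_cohort(3, 4, subject_params(), seed = 9)
  c2 <- generate_cohort(3, 4, subject_params(), seed = 9)
  expect_identical(c1, c2)
})

test_that("cohorts have the requested sizes and labels", {
  co <- generate_cohort(4, 7, subject_params(), seed = 2)
  expect_length(co, 11)
  labs <- vapply(co, `[[`, character(1), "label")
  expect_equal(sum(labs == "PB"), 4)
  expect_equal(sum(labs == "nPB"), 7)
  amps <- vapply(co, function(s) attr(s, "params")$pb_amplitude,
                 numeric(1))
  expect_true(all(amps[labs == "PB"] >= 0.2 & amps[labs == "PB"] <= 0.5))
  expect_true(all(amps[labs == "nPB"] <= 0.02))
  expect_identical(generate_cohort(0, 0, subject_params(), seed = 1),
                   list())
})

test_that("trend-only series leaves >= 99% of energy in the EMD residue", {
  s <- generate_subject(subject_params(pb_amplitude = 0,
                                       noise_sigma = 0, gasp_prob = 0))
  kept <- filter_mee(s)$kept
  d <- emd(kept)
  expect_gte(sum(d$residue^2) / sum(kept^2), 0.99)
})
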