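test_that("count_peaks equals the closed form on clean sinusoids", {
  i <- 0:195
  expect_equal(count_peaks(sin(2 * pi * i / 14)), 14L)  # 14 full cycles
  expect_equal(count_peaks(rep(0, 50)), 0L)
  expect_error(count_peaks(c(1, 2)), "too short")
})

test_that("count_peaks matches the exhaustive prominence oracle", {
  set.seed(123)
  for (r in 1:50) {
    kind <- r %% 3
    x <- if (kind == 0) stats::rnorm(150)
         else if (kind == 1)
           sin(2 * pi * (0:149) / sample(5:40, 1)) +
             0.3 * stats::rnorm(150)
         else round(stats::rnorm(150), 1)     # many ties/plateaus
    expect_identical(count_peaks(x), oracle_count_peaks(x))
  }
  # noisy sinusoid keeps exactly its cycle count
  set.seed(7)
  x <- sin(2 * pi * (0:199) / 20) + stats::runif(200, -0.1, 0.1)
  expect_equal(count_peaks(x), 10L)
})

test_that("feature vectors follow the decomposition and scale invariance", {
  tt <- two_tone(drift = 0)
  d <- emd(tt$x)
  f <- features_for_subject(d, subject_id = "t1", label = "PB")
  expect_equal(unname(f$deltas[1]), 25L)   # 200/8 cycles of the fast tone
  expect_equal(unname(f$deltas[2]), 4L)    # 200/50 cycles of the slow tone
  d10 <- emd(10 * tt$x)
  f10 <- features_for_subject(d10)
  expect_equal(unname(f10$deltas), unname(f$deltas))
})

test_that("pooled t-test matches the textbook formula and stats::t.test", {
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  tt <- ttest_two_sample(a, b)
  # hand-computed pooled form
  sp2 <- ((2) * stats::var(a) + (2) * stats::var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$p, 2 * stats::pt(-abs(t_hand), 4), tolerance = 1e-12)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
  refw <- stats::t.test(a, b)
  ttw <- ttest_two_sample(a, b, variant = "welch")
  expect_equal(ttw$p, refw$p.value, tolerance = 1e-12)
  # degenerate conventions
  same <- ttest_two_sample(c(2, 2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(ttest_two_sample(1, c(1, 2)), "at least 2")
  expect_error(ttest_two_sample(c(1, 1), c(2, 2)), "undefined")
})

test_that("t-test p agrees with a permutation oracle on random groups", {
  # group size 15: large enough for the permutation distribution of the
  # mean difference to match the t reference within 0.02
  set.seed(55)
  for (r in 1:8) {
    a <- stats::rnorm(15, mean = stats::runif(1, 0, 1))
    b <- stats::rnorm(15)
    p_t <- ttest_two_sample(a, b)$p
    p_perm <- oracle_permutation_p(a, b, n_perm = 20000L)
    expect_lt(abs(p_t - p_perm), 0.02)
  }
})

test_that("label swap flips t and preserves p", {
  feats <- features_from_table(published_peak_counts())
  cmp <- compare_cohorts(feats)
  swapped <- lapply(feats, function(f) {
    f$label <- if (f$label == "PB") "nPB" else "PB"
    f
  })
  cmp2 <- compare_cohorts(swapped)
  expect_equal(cmp2$t, -cmp$t)
  expect_equal(cmp2$p, cmp$p)
})

test_that("published peak counts give the printed significance pattern", {
  feats <- features_from_table(published_peak_counts())
  for (variant in c("pooled", "welch")) {
    cmp <- compare_cohorts(feats, variant = variant)
    expect_equal(nrow(cmp), 5)
    expect_gt(cmp$p[1], 0.1)
    expect_gt(cmp$p[2], 0.1)
    expect_lt(cmp$p[3], 0.02)
    expect_lt(cmp$p[4], 0.02)
  }
})

test_that("compare_cohorts validates groups and trims to common IMFs", {
  feats <- features_from_table(published_peak_counts())
  expect_error(compare_cohorts(feats[1:10]), "each of the PB and nPB")
  # drop delta5 for one subject: comparison stops at delta4
  feats[[1]]$deltas <- feats[[1]]$deltas[1:4]
  cmp <- compare_cohorts(feats)
  expect_equal(nrow(cmp), 4)
})

test_that("identically generated groups rarely reach significance", {
  # null calibration of the end-to-end feature comparison (scaled down:
  # 20 cohorts of 5+5, no PB modulation in either group)
  set.seed(66)
  frac_sig <- numeric(0)
  hits <- matrix(0L, nrow = 20, ncol = 2)
  for (cs in 1:20) {
    cohort <- generate_cohort(5, 5, subject_params(), seed = 1000L + cs,
                              pb_range = c(0, 0.02))
    feats <- lapply(cohort, function(s) {
      d <- emd(filter_mee(s)$kept)
      features_for_subject(d, subject_id = s$subject_id,
                           label = s$label)
    })
    cmp <- compare_cohorts(feats)
    hits[cs, ] <- as.integer(cmp$p[cmp$imf_index %in% c(1, 2)] < 0.05)
  }
  expect_lte(mean(hits[, 1]), 0.15)
  expect_lte(mean(hits[, 2]), 0.15)
})
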