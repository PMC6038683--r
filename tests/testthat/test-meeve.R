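test_that("select_window returns the k breaths before the peak", {
  ve <- c(seq(10, 60, length.out = 250), seq(59, 40, length.out = 50))
  s <- breath_series(seq_along(ve), ve)
  expect_equal(select_window(s, k = 200), c(50L, 249L))  # peak at 250
  expect_error(select_window(breath_series(1:150, seq(1, 2, length.out = 150)),
                             k = 200), "insufficient history")
  short <- select_window(breath_series(1:150, seq(1, 2, length.out = 150)),
                         k = 200, allow_short = TRUE)
  expect_equal(short, c(1L, 149L))
  # all ties: first occurrence wins, so there is no pre-peak window
  const <- breath_series(1:50, rep(5, 50))
  expect_error(select_window(const), "peak at series start")
})

test_that("fit_ar recovers exact AR relations to machine precision", {
  y <- numeric(50); y[1] <- 10
  for (t in 2:50) y[t] <- 2 + 0.5 * y[t - 1]
  m <- fit_ar(y, p = 1)
  expect_equal(m$c, 2, tolerance = 1e-10)
  expect_equal(m$phi, 0.5, tolerance = 1e-10)
  # zero-residual fit: predictions reproduce the observations
  expect_equal(predict_ar(m, y), y[-1], tolerance = 1e-8)
  expect_error(fit_ar(rep(3, 40), p = 6), "degenerate")
  expect_error(fit_ar(1:10, p = 6), "too short")
})

test_that("fit_ar recovers noisy AR(6) coefficients on average", {
  phi_true <- c(0.4, 0.15, -0.1, 0.05, 0.1, -0.05)
  errs <- vapply(1:100, function(r) {
    y <- simulate_ar(1, phi_true, n = 200, sigma = 0.5, seed = r)
    mean(abs(fit_ar(y, p = 6)$phi - phi_true))
  }, numeric(1))
  expect_lt(mean(errs), 0.15)
})

test_that("predict_ar is one-step-ahead from observed values", {
  ident <- structure(list(c = 0, phi = 1, p = 1L), class = "ar_model")
  expect_equal(predict_ar(ident, c(10, 10, 7, 10)), c(10, 10, 7))
  const5 <- structure(list(c = 5, phi = 0, p = 1L), class = "ar_model")
  expect_equal(predict_ar(const5, c(1, 99, 3, 7)), rep(5, 3))
  expect_error(predict_ar(ident, 10), "must exceed order")
})

test_that("filter rule matches the hand-computed toy example", {
  ident <- structure(list(c = 0, phi = 1, p = 1L), class = "ar_model")
  res <- filter_window(c(10, 10, 7, 10), model = ident, threshold = 0.8)
  expect_equal(res$predictions, c(10, 10, 7))
  expect_equal(res$removed_indices, 3L)  # the 7: 7 < 0.8 * 10
  expect_equal(res$kept, c(10, 10, 10))
})

test_that("conservation and monotone-threshold properties hold", {
  s <- generate_subject(subject_params(pb_amplitude = 0.3,
                                       gasp_prob = 0.05, seed = 13))
  res8 <- filter_mee(s, threshold = 0.8)
  expect_equal(length(res8$kept) + length(res8$removed_indices), res8$k)
  res7 <- filter_window(res8$window_ve, model = res8$model,
                        threshold = 0.7)
  expect_true(all(res7$removed_indices %in% res8$removed_indices))
  # removed breaths all satisfy the rule against the predictions
  p <- res8$model$p
  expect_true(all(res8$window_ve[res8$removed_indices] <
                    0.8 * res8$predictions[res8$removed_indices - p]))
})

test_that("filter is a no-op on series the model predicts exactly", {
  y <- numeric(60); y[1] <- 30
  for (t in 2:60) y[t] <- 1 + 0.9 * y[t - 1]
  res <- filter_window(y, p = 1)
  expect_length(res$removed_indices, 0)
  expect_equal(res$kept, y)
})

test_that("noise-free subjects without gasps lose no breaths", {
  s <- generate_subject(subject_params(pb_amplitude = 0.35,
                                       noise_sigma = 0, gasp_prob = 0,
                                       seed = 4))
  expect_length(filter_mee(s)$removed_indices, 0)
})

test_that("every noise-free gasp event is detected", {
  # each artifact event contributes two adjacent low breaths; the first
  # is predicted from normal predecessors and always falls below the
  # threshold, so the event is always caught (the second member's
  # prediction is contaminated by the first, hence event level here;
  # index-level recall is exercised in the acceptance suite)
  for (seed in c(1L, 2L, 3L)) {
    s <- generate_subject(subject_params(noise_sigma = 0,
                                         gasp_prob = 0.05, seed = seed))
    g <- attr(s, "gasp_indices")
    mee <- filter_mee(s)
    win <- mee$window_start:mee$window_end
    g_in <- which(win %in% g)
    events <- split(g_in, cumsum(c(1, diff(g_in) != 1)))
    events <- Filter(function(e) any(e > mee$model$p), events)
    detected <- vapply(events,
                       function(e) any(e %in% mee$removed_indices),
                       logical(1))
    expect_true(all(detected))
  }
})
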