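#' Select the pre-peak analysis window
#'
#' Periodic breathing is most pronounced near peak exertion, so the
#' analysis uses the `k` breaths immediately preceding the global
#' ventilation maximum (about 4-6 minutes of exercise at the breath
#' rates seen near peak).  The peak breath itself is excluded; ties on
#' the maximum resolve to the first occurrence.
#'
#' @param series a [breath_series()].
#' @param k window length in breaths (default 200).
#' @param allow_short if `TRUE`, a series with fewer than `k` pre-peak
#'   breaths yields the shorter window from the start of the series
#'   instead of an error.
#' @return Integer vector `c(start, end)`: 1-based index interval
#'   `[start, end]` (inclusive) into the series, of length `k` (or less
#'   under `allow_short`).
#' @export
select_window <- function(series, k = 200L, allow_short = FALSE) {
  stopifnot(inherits(series, "breath_series"))
  k <- as.integer(k)
  i_max <- which.max(series$ve)          # first occurrence on ties
  if (i_max == 1L)
    stop("peak at series start: no pre-peak window exists",
         call. = FALSE)
  if (i_max - 1L < k) {
    if (!allow_short)
      stop(sprintf("insufficient history: only %d breaths precede the peak (need %d)",
                   i_max - 1L, k), call. = FALSE)
    return(c(1L, i_max - 1L))
  }
  c(i_max - k, i_max - 1L)
}

#' Fit an autoregressive model by least squares
#'
#' Fits `y_t = c + phi_1 y_{t-1} + ... + phi_p y_{t-p}` by ordinary
#' least squares on the lag matrix with intercept, minimising the sum of
#' squared one-step prediction errors over `t = p+1 .. N`.  When the
#' data satisfy an exact AR(p) relation with a full-rank lag matrix the
#' coefficients are recovered to machine precision.
#'
#' @param window numeric VE sequence.
#' @param p model order (default 6).
#' @return An object of class `ar_model`: list with `c` (intercept),
#'   `phi` (length-`p` coefficients) and `p`.
#' @export
fit_ar <- function(window, p = 6L) {
  p <- as.integer(p)
  n <- length(window)
  if (p < 1L) stop("order p must be >= 1", call. = FALSE)
  if (n <= 2L * p + 1L)
    stop(sprintf("window too short for AR(%d): need > %d samples, got %d",
                 p, 2L * p + 1L, n), call. = FALSE)
  if (max(window) == min(window))
    stop("degenerate series: constant window, AR fit unidentifiable",
         call. = FALSE)
  y <- window[(p + 1L):n]
  X <- cbind(1, vapply(seq_len(p),
                       function(j) window[(p + 1L - j):(n - j)],
                       numeric(n - p)))
  # minimum-norm least squares via SVD: identical to plain OLS when the
  # lag matrix has full rank, and still well-defined on the numerically
  # collinear windows produced by smooth noise-free ramps (predictions,
  # which are all the filter uses, are the unique projection either way)
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-12
  if (!any(keep))
    stop("degenerate series: lag matrix is rank deficient (constant window?)",
         call. = FALSE)
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
  beta <- drop(beta)
  structure(list(c = unname(beta[1]), phi = unname(beta[-1]), p = p),
            class = "ar_model")
}

#' One-step-ahead AR predictions
#'
#' Computes the predicted ventilation for each breath from its `p`
#' observed predecessors (never from earlier predictions), which is the
#' quantity each observation is compared against in the gasp filter.
#'
#' @param model an `ar_model` from [fit_ar()].
#' @param window numeric sequence of length `> p`.
#' @return Numeric vector of predictions for `t = p+1 .. N` (length
#'   `N - p`).
#' @export
predict_ar <- function(model, window) {
  stopifnot(inherits(model, "ar_model"))
  p <- model$p
  n <- length(window)
  if (n <= p)
    stop(sprintf("window length %d must exceed order %d", n, p),
         call. = FALSE)
  lag <- vapply(seq_len(p), function(j) window[(p + 1L - j):(n - j)],
                numeric(n - p))
  drop(model$c + lag %*% model$phi)
}

#' @export
predict.ar_model <- function(object, window, ...) predict_ar(object, window)

#' Extract the most exhausted exercise ventilations (MEE-Ve)
#'
#' The full preprocessing stage: selects the `k`-breath pre-peak window,
#' fits an AR(`p`) model once on the raw window, computes one-step-ahead
#' predictions, and removes every breath whose observed VE falls below
#' `threshold` times its prediction (the signature of a gasping
#' exhalation recorded as spuriously low breaths).  Filtering is a
#' single pass with no refit; the first `p` breaths, which have no
#' prediction, are always kept.  Removed breaths are deleted, so the
#' output series is re-indexed consecutively.
#'
#' @param series a [breath_series()].
#' @param k window length (default 200).
#' @param p AR order (default 6).
#' @param threshold removal threshold on the ratio y/yhat (default 0.8).
#' @param allow_short passed to [select_window()].
#' @param model optional pre-specified `ar_model`, mainly for testing;
#'   when supplied the fit step is skipped.
#' @return An object of class `meeve_result`: list with `window_start`,
#'   `window_end` (1-based inclusive indices into `series`), `kept`
#'   (filtered VE sequence, the MEE-Ve signal), `kept_indices` and
#'   `removed_indices` (window-relative, 1-based), `predictions` (for
#'   `t = p+1 ..` within the window), `model`, `threshold`, `k`.
#' @export
filter_mee <- function(series, k = 200L, p = 6L, threshold = 0.8,
                       allow_short = FALSE, model = NULL) {
  win <- select_window(series, k = k, allow_short = allow_short)
  y <- series$ve[win[1]:win[2]]
  res <- filter_window(y, p = p, threshold = threshold, model = model)
  res$window_start <- win[1]
  res$window_end <- win[2]
  res
}

#' Apply the AR gasp filter to a raw window
#'
#' The filtering core of [filter_mee()], usable on any numeric window:
#' fit (or take) an AR model, predict one step ahead from observed
#' predecessors, and remove every breath with
#' `y_t < threshold * yhat_t`.
#'
#' @param y numeric VE window.
#' @param p AR order; ignored when `model` is given.
#' @param threshold removal threshold.
#' @param model optional pre-specified `ar_model`.
#' @return A `meeve_result` (with `window_start`/`window_end` of
#'   `1`/`length(y)`).
#' @export
filter_window <- function(y, p = 6L, threshold = 0.8, model = NULL) {
  if (is.null(model)) model <- fit_ar(y, p = p) else p <- model$p
  yhat <- predict_ar(model, y)
  t_pred <- (p + 1L):length(y)
  removed <- t_pred[y[t_pred] < threshold * yhat]
  kept_idx <- setdiff(seq_along(y), removed)
  structure(list(window_start = 1L, window_end = length(y),
                 window_ve = y,
                 kept = y[kept_idx], kept_indices = kept_idx,
                 removed_indices = removed, predictions = yhat,
                 model = model, threshold = threshold,
                 k = length(y)),
            class = "meeve_result")
}

#' @export
print.meeve_result <- function(x, ...) {
  cat(sprintf("<meeve_result> window [%d, %d], AR(%d), threshold %.2f: kept %d, removed %d\n",
              x$window_start, x$window_end, x$model$p, x$threshold,
              length(x$kept), length(x$removed_indices)))
  invisible(x)
}
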