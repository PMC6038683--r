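#' Summarise an IMF by mean period and energy density
#'
#' The white-noise screening operates in the (mean period, energy)
#' plane.  Energy is the mean squared value per sample,
#' `E = mean(imf^2)`; the mean period is `N` divided by the number of
#' interior maxima (one oscillation per peak), with the degenerate
#' zero-peak case assigned period `N`.
#'
#' @param imf numeric sequence, length >= 4.
#' @param index IMF index `j`, carried through for reporting.
#' @return List of class `imf_summary` with `index`, `mean_period`
#'   (breaths), `energy`, `log_period` and `log_energy` (natural logs).
#' @export
summarize_imf <- function(imf, index = NA_integer_) {
  n <- length(imf)
  if (n < 4L) stop("sequence too short: need length >= 4", call. = FALSE)
  energy <- mean(imf^2)
  n_peaks <- length(find_extrema(imf)$maxima)
  mean_period <- if (n_peaks == 0L) n else n / n_peaks
  structure(list(index = index, mean_period = mean_period,
                 energy = energy, log_period = log(mean_period),
                 log_energy = if (energy > 0) log(energy) else -Inf),
            class = "imf_summary")
}

#' Monte-Carlo white-noise null for IMF energy
#'
#' Simulates `n_null` unit-variance Gaussian white-noise series of
#' length `N`, EMD-decomposes each, and pools the (log mean period,
#' log energy) pairs of every resulting IMF.  Log periods are binned
#' into `n_bins` equal-width bins; the per-bin upper quantiles of log
#' energy at each confidence level are interpolated linearly between
#' bin centres and made non-increasing in log period (the theoretical
#' energy-period relation for white-noise IMFs is decreasing; the
#' running-maximum correction removes Monte-Carlo jitter in sparse
#' long-period bins).
#'
#' @param N series length the null is built for.
#' @param n_null number of noise realisations (default 1000; fewer
#'   than 100 triggers a stability warning).
#' @param seed RNG seed.
#' @param levels confidence levels (default `c(0.95, 0.99)`).
#' @param n_bins number of log-period bins (default 20).
#' @return Object of class `null_curves`: list with `levels`, `curves`
#'   (one interpolating function per level, mapping log period to the
#'   null upper quantile of log energy), `points` (the pooled null
#'   scatter, a data.frame), `N`, `n_null`, `seed`.
#' @export
null_ensemble <- function(N, n_null = 1000L, seed = 1L,
                          levels = c(0.95, 0.99), n_bins = 20L) {
  if (N < 32L) stop("N must be >= 32 for a stable null", call. = FALSE)
  if (n_null < 100L)
    warning("n_null < 100: null curves may be unstable", call. = FALSE)
  set.seed(as.integer(seed))
  lp <- le <- vector("list", n_null)
  for (r in seq_len(n_null)) {
    w <- stats::rnorm(N)
    w <- w / stats::sd(w)                      # exact unit variance
    d <- emd(w)
    if (d$n == 0L) next
    s <- lapply(seq_len(d$n), function(j) summarize_imf(d$imfs[, j], j))
    lp[[r]] <- vapply(s, `[[`, numeric(1), "log_period")
    le[[r]] <- vapply(s, `[[`, numeric(1), "log_energy")
  }
  pts <- data.frame(log_period = unlist(lp), log_energy = unlist(le))
  pts <- pts[is.finite(pts$log_energy), ]
  brk <- seq(min(pts$log_period), max(pts$log_period),
             length.out = n_bins + 1L)
  bin <- findInterval(pts$log_period, brk, rightmost.closed = TRUE)
  centres <- (brk[-1] + brk[-length(brk)]) / 2
  curves <- lapply(levels, function(lev) {
    q <- tapply(pts$log_energy, factor(bin, levels = seq_len(n_bins)),
                stats::quantile, probs = lev, names = FALSE)
    ok <- !is.na(q)
    x <- centres[ok]
    y <- as.numeric(q[ok])
    y <- rev(cummax(rev(y)))                  # enforce non-increasing
    stats::approxfun(x, y, rule = 2)
  })
  names(curves) <- sprintf("%g", levels)
  structure(list(levels = levels, curves = curves, points = pts,
                 N = N, n_null = n_null, seed = as.integer(seed)),
            class = "null_curves")
}

#' Test IMFs against the white-noise null
#'
#' Rescales the reconstructed input series to unit variance (so the
#' comparison is on the null's scale and the flags are invariant to
#' input scaling), summarises each IMF, and flags it significant at a
#' level when its log energy exceeds the null upper-quantile curve at
#' its log period.
#'
#' @param imfset an `imf_set` from [emd()].
#' @param levels confidence levels (default `c(0.95, 0.99)`).
#' @param n_null Monte-Carlo realisations for the null (default 1000).
#' @param seed RNG seed for the null ensemble.
#' @param null optional precomputed [null_ensemble()] for the same
#'   series length (reuse across subjects to amortise the simulation);
#'   its levels must contain `levels`.
#' @return Object of class `significance_result`: list with
#'   `summaries` (data.frame: index, mean_period, energy, log_period,
#'   log_energy), `flags` (logical matrix, IMFs x levels), `levels`,
#'   `null` (the `null_curves` used).
#' @export
test_imfs <- function(imfset, levels = c(0.95, 0.99), n_null = 1000L,
                      seed = 1L, null = NULL) {
  stopifnot(inherits(imfset, "imf_set"))
  if (imfset$n == 0L)
    stop("imf_set is empty: nothing to test", call. = FALSE)
  N <- length(imfset$residue)
  if (is.null(null)) {
    null <- null_ensemble(N, n_null = n_null, seed = seed,
                          levels = if (length(levels)) levels
                                   else c(0.95, 0.99))
  } else {
    if (null$N != N)
      stop(sprintf("null was built for length %d, series has length %d",
                   null$N, N), call. = FALSE)
    if (!all(levels %in% null$levels))
      stop("requested levels not present in supplied null", call. = FALSE)
  }
  x <- rowSums(imfset$imfs) + imfset$residue
  s <- stats::sd(x)
  scale <- if (s > 0) 1 / s else 1
  summ <- lapply(seq_len(imfset$n),
                 function(j) summarize_imf(imfset$imfs[, j] * scale, j))
  df <- data.frame(index = vapply(summ, `[[`, numeric(1), "index"),
                   mean_period = vapply(summ, `[[`, numeric(1),
                                        "mean_period"),
                   energy = vapply(summ, `[[`, numeric(1), "energy"),
                   log_period = vapply(summ, `[[`, numeric(1),
                                       "log_period"),
                   log_energy = vapply(summ, `[[`, numeric(1),
                                       "log_energy"))
  flags <- matrix(FALSE, nrow = imfset$n, ncol = length(levels),
                  dimnames = list(NULL, sprintf("%g", levels)))
  for (l in seq_along(levels)) {
    f <- null$curves[[sprintf("%g", levels[l])]]
    flags[, l] <- df$log_energy > f(df$log_period)
  }
  structure(list(summaries = df, flags = flags, levels = levels,
                 null = null),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  df <- x$summaries
  for (l in seq_along(x$levels))
    df[[paste0("sig", sprintf("%g", x$levels[l]))]] <- x$flags[, l]
  cat("<significance_result>\n")
  print(df, row.names = FALSE)
  invisible(x)
}
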