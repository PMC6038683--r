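#' Locate interior extrema
#'
#' Strict local maxima and minima, with two conventions needed by the
#' sifting loop: a plateau (run of equal values) contributes its first
#' sample only, and the endpoints of the sequence are never reported.
#'
#' @param x numeric sequence, length >= 3.
#' @return List with integer vectors `maxima` and `minima` (1-based).
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) stop("sequence too short: need length >= 3", call. = FALSE)
  r <- rle(x)
  m <- length(r$values)
  if (m < 3L) return(list(maxima = integer(0), minima = integer(0)))
  starts <- cumsum(c(1L, r$lengths[-m]))   # first sample of each run
  v <- r$values
  i <- 2:(m - 1L)
  is_max <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
  is_min <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
  list(maxima = starts[i[is_max]], minima = starts[i[is_min]])
}

# Natural cubic spline envelope through (idx, val), with the two
# nearest extrema mirrored across each end of the 1..n index range to
# suppress end swings.  Returns the envelope evaluated at 1..n.
spline_envelope <- function(idx, val, n) {
  k <- length(idx)
  lm <- min(2L, k)                          # points mirrored per side
  left_i <- 2 - idx[seq_len(lm)]           # reflect about sample 1
  right_i <- 2 * n - idx[k - seq_len(lm) + 1L]  # reflect about sample n
  xi <- c(rev(left_i), idx, rev(right_i))
  yi <- c(rev(val[seq_len(lm)]), val, rev(val[k - seq_len(lm) + 1L]))
  keep <- !duplicated(xi)
  f <- stats::splinefun(xi[keep], yi[keep], method = "natural")
  f(seq_len(n))
}

#' One sifting iteration
#'
#' Subtracts the local envelope mean from a signal: cubic-spline upper
#' and lower envelopes are drawn through the maxima and minima (with
#' mirrored boundary extrema), averaged, and removed.  Iterating this
#' operation is what isolates an intrinsic mode function.
#'
#' @param x numeric sequence with at least 2 maxima and 2 minima.
#' @return The candidate component `x - m(t)`.
#' @export
sift_once <- function(x) {
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L)
    stop("residue reached: fewer than 2 maxima or 2 minima",
         call. = FALSE)
  n <- length(x)
  upper <- spline_envelope(ex$maxima, x[ex$maxima], n)
  lower <- spline_envelope(ex$minima, x[ex$minima], n)
  x - (upper + lower) / 2
}

#' Extract a single intrinsic mode function
#'
#' Repeats [sift_once()] until the normalised squared change between
#' consecutive sifts,
#' `SD = sum((h_prev - h)^2) / sum(h_prev^2)`, drops below `sd_stop`
#' (Cauchy-type stopping criterion; the classical operating range is
#' 0.2-0.3) AND the component is well formed (extrema and zero-crossing
#' counts differ by at most one), or `max_sift` iterations are reached.
#' The Cauchy criterion alone can stop on components still carrying
#' riding waves; the well-formedness condition is the classical
#' companion check.  If the envelopes become unbuildable mid-way the
#' component is finalised as is.
#'
#' @param x numeric sequence.
#' @param sd_stop stopping tolerance (default 0.2).
#' @param max_sift iteration cap (default 50).
#' @return The extracted IMF (same length as `x`).
#' @export
extract_imf <- function(x, sd_stop = 0.2, max_sift = 50L) {
  h <- sift_once(x)                        # errors if residue reached
  for (i in seq_len(max_sift - 1L)) {
    h_new <- tryCatch(sift_once(h), error = function(e) NULL)
    if (is.null(h_new)) return(h)
    denom <- sum(h^2)
    sd_val <- if (denom > 0) sum((h - h_new)^2) / denom else 0
    h <- h_new
    if (sd_val < sd_stop && is_well_formed_imf(h)) break
  }
  h
}

# extrema count vs zero-crossing count differ by at most `tol`
is_well_formed_imf <- function(x, tol = 1L) {
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  s <- sign(x)
  s <- s[s != 0]
  n_zc <- sum(diff(s) != 0)
  abs(n_ext - n_zc) <= tol
}

#' Empirical mode decomposition
#'
#' Iteratively extracts IMFs from successive residues until the residue
#' is monotone or has too few extrema to envelope, or `max_imfs` is
#' reached.  By construction the components telescope: the sum of all
#' IMFs plus the residue reproduces the input exactly (up to floating
#' point).  IMFs are ordered fast to slow (IMF 1 carries the highest
#' mean frequency).
#'
#' @param x numeric sequence, length >= 8.
#' @param max_imfs cap on the number of IMFs (default 10).
#' @param sd_stop,max_sift passed to [extract_imf()].
#' @return An object of class `imf_set`: list with `imfs` (an
#'   `N x n` matrix, one IMF per column), `residue` (length `N`) and
#'   `n` (number of IMFs, possibly 0).
#' @examples
#' x <- sin(2 * pi * (0:199) / 8) + sin(2 * pi * (0:199) / 50)
#' d <- emd(x)
#' d$n
#' @export
emd <- function(x, max_imfs = 10L, sd_stop = 0.2, max_sift = 50L) {
  n <- length(x)
  if (n < 8L) stop("sequence too short for EMD: need length >= 8",
                   call. = FALSE)
  residue <- as.numeric(x)
  imfs <- list()
  while (length(imfs) < max_imfs) {
    ex <- find_extrema(residue)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) break
    imf <- extract_imf(residue, sd_stop = sd_stop, max_sift = max_sift)
    imfs[[length(imfs) + 1L]] <- imf
    residue <- residue - imf
  }
  m <- if (length(imfs))
    matrix(unlist(imfs), nrow = n,
           dimnames = list(NULL, paste0("imf", seq_along(imfs))))
  else matrix(numeric(0), nrow = n, ncol = 0)
  structure(list(imfs = m, residue = residue, n = length(imfs)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs of length %d (+ residue)\n",
              x$n, length(x$residue)))
  invisible(x)
}

# Unwrap phase angles so consecutive differences lie in (-pi, pi].
unwrap_phase <- function(theta) {
  d <- diff(theta)
  jumps <- round(d / (2 * pi))
  theta - c(0, cumsum(jumps)) * 2 * pi
}

#' Analytic-signal (Hilbert) analysis of one IMF
#'
#' Builds the discrete analytic signal by suppressing negative
#' frequencies in the Fourier domain, yielding the quadrature component
#' `Y(t)`; amplitude is `sqrt(C^2 + Y^2)`, phase is the unwrapped
#' angle, and instantaneous frequency is the forward first difference
#' of phase over `2*pi`.  Because breaths are irregular in time, the
#' time base is breath index and the frequency unit is cycles per
#' breath.
#'
#' @param imf numeric sequence, length >= 8, approximately zero-mean.
#' @return An object of class `analytic_imf`: list with `amplitude`
#'   (length `N`, non-negative), `phase` (length `N`, radians,
#'   unwrapped) and `inst_freq` (length `N - 1`, cycles/breath).
#' @export
hilbert_analytic <- function(imf) {
  n <- length(imf)
  if (n < 8L) stop("sequence too short: need length >= 8", call. = FALSE)
  X <- stats::fft(imf)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  amplitude <- Mod(z)
  phase <- unwrap_phase(Arg(z))
  structure(list(amplitude = amplitude, phase = phase,
                 inst_freq = diff(phase) / (2 * pi)),
            class = "analytic_imf")
}

#' Hilbert-Huang transform of a sequence
#'
#' Convenience wrapper: [emd()] followed by [hilbert_analytic()] on
#' every IMF.
#'
#' @param x numeric sequence.
#' @param ... passed to [emd()].
#' @return List with the `imf_set` (`$decomposition`) and a list of
#'   `analytic_imf` objects (`$analytic`), one per IMF.
#' @export
hht <- function(x, ...) {
  d <- emd(x, ...)
  list(decomposition = d,
       analytic = lapply(seq_len(d$n),
                         function(j) hilbert_analytic(d$imfs[, j])))
}
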