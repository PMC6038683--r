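# Independent oracles and fixture builders, deliberately naive.

# Exhaustive O(n^2) topographic-prominence scan: for each strict interior
# local maximum (plateau -> first sample), walk outward to the nearest
# strictly higher sample on each side and take the minimum of each
# stretch; prominence is height minus the larger of the two minima.
oracle_count_peaks <- function(x, prominence_frac = 0.5) {
  n <- length(x)
  rms <- sqrt(mean(x^2))
  if (rms == 0) return(0L)
  count <- 0L
  i <- 2L
  while (i <= n - 1L) {
    # plateau-aware local max test at first sample of a run
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    if (j <= n - 1L && x[i] > x[i - 1L] && x[i] > x[j + 1L] &&
        x[i] > 0) {
      h <- x[i]
      lmin <- Inf
      for (t in (i - 1L):1L) {
        if (x[t] > h) break
        lmin <- min(lmin, x[t])
      }
      rmin <- Inf
      for (t in (j + 1L):n) {
        if (x[t] > h) break
        rmin <- min(rmin, x[t])
      }
      if (h - max(lmin, rmin) >= prominence_frac * rms)
        count <- count + 1L
    }
    i <- j + 1L
  }
  count
}

# Monte-Carlo permutation two-sample test (difference of means).
oracle_permutation_p <- function(a, b, n_perm = 20000L) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1L) / (n_perm + 1L)
}

# Two-tone fixture: fast + slow sinusoid on a mild drift.
two_tone <- function(n = 200L, fast = 8, slow = 50, drift = 0.01) {
  i <- seq_len(n) - 1L
  list(x = sin(2 * pi * i / fast) + sin(2 * pi * i / slow) + drift * i,
       fast = sin(2 * pi * i / fast),
       slow = sin(2 * pi * i / slow),
       central = seq.int(floor(n * 0.1) + 1L, ceiling(n * 0.9)))
}

# Simulate a stationary AR(p) series with intercept by direct recursion.
simulate_ar <- function(c0, phi, n, sigma, burn = 200L, seed = 1L) {
  set.seed(seed)
  p <- length(phi)
  ntot <- n + burn
  y <- numeric(ntot)
  mu <- c0 / (1 - sum(phi))
  y[seq_len(p)] <- mu
  for (t in (p + 1L):ntot)
    y[t] <- c0 + sum(phi * y[(t - 1L):(t - p)]) + stats::rnorm(1, 0, sigma)
  y[(burn + 1L):ntot]
}

# Count extrema and zero crossings of a component, for the IMF
# well-formedness check.
imf_counts <- function(x) {
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  s <- sign(x)
  s <- s[s != 0]
  n_zc <- sum(diff(s) != 0)
  c(extrema = n_ext, zero_crossings = n_zc)
}
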