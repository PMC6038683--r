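#' Parameter set for a synthetic CPET subject
#'
#' Bundles the physiological and nuisance parameters that drive
#' [generate_subject()].  Defaults describe a 13-minute incremental test:
#' respiratory rate ramps from a resting 15 breaths/min to 40 breaths/min
#' at peak exercise (adult resting rates are 12-20/min, rising to
#' 30-50/min under load), while minute ventilation ramps from 10 to
#' 60 L/min and decays back during recovery.
#'
#' @param rest_rate resting respiratory rate, breaths/min.
#' @param peak_rate peak-exercise respiratory rate, breaths/min; must
#'   exceed `rest_rate`.
#' @param ve_rest resting minute ventilation, L/min.
#' @param ve_peak peak minute ventilation, L/min; must exceed `ve_rest`.
#' @param exercise_duration length of the incremental (ramp) phase, s.
#' @param recovery_duration length of the recovery phase, s.
#' @param pb_amplitude periodic-breathing modulation depth `m` in
#'   `[0, 1)`; 0 disables the oscillation (a non-PB subject).
#' @param pb_period periodic-breathing cycle length, s.
#' @param noise_sigma standard deviation of the multiplicative lognormal
#'   measurement noise on the log scale; 0 disables noise.
#' @param gasp_prob per-breath probability that an irregular gasping
#'   exhalation is recorded as two spuriously low breaths.
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#'
#' @return An object of class `subject_params` (a validated list).
#' @seealso [generate_subject()], [generate_cohort()]
#' @export
subject_params <- function(rest_rate = 15, peak_rate = 40,
                           ve_rest = 10, ve_peak = 60,
                           exercise_duration = 600,
                           recovery_duration = 180,
                           pb_amplitude = 0, pb_period = 60,
                           noise_sigma = 0.08, gasp_prob = 0.03,
                           seed = 1L) {
  p <- list(rest_rate = rest_rate, peak_rate = peak_rate,
            ve_rest = ve_rest, ve_peak = ve_peak,
            exercise_duration = exercise_duration,
            recovery_duration = recovery_duration,
            pb_amplitude = pb_amplitude, pb_period = pb_period,
            noise_sigma = noise_sigma, gasp_prob = gasp_prob,
            seed = as.integer(seed))
  validate_subject_params(p)
  class(p) <- "subject_params"
  p
}

validate_subject_params <- function(p) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid parameter '%s': %s", field, msg),
                  call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("rest_rate", "peak_rate", "ve_rest", "ve_peak",
              "exercise_duration", "recovery_duration", "pb_amplitude",
              "pb_period", "noise_sigma", "gasp_prob"))
    chk(num1(p[[f]]), f, "must be a single finite number")
  chk(p$rest_rate > 0, "rest_rate", "must be > 0")
  chk(p$rest_rate < p$peak_rate, "peak_rate", "must exceed rest_rate")
  chk(p$ve_rest > 0, "ve_rest", "must be > 0")
  chk(p$ve_rest < p$ve_peak, "ve_peak", "must exceed ve_rest")
  chk(p$exercise_duration > 0, "exercise_duration", "must be > 0")
  chk(p$recovery_duration >= 0, "recovery_duration", "must be >= 0")
  chk(p$pb_amplitude >= 0 && p$pb_amplitude < 1, "pb_amplitude",
      "must lie in [0, 1)")
  chk(p$pb_period > 0, "pb_period", "must be > 0")
  chk(p$noise_sigma >= 0, "noise_sigma", "must be >= 0")
  chk(p$gasp_prob >= 0 && p$gasp_prob < 1, "gasp_prob",
      "must lie in [0, 1)")
  invisible(p)
}

#' Construct a breath-by-breath ventilation series
#'
#' The core container of the package: one minute-ventilation (VE) value
#' per breath, ordered in time.  All analysis modules index by breath
#' number, so irregular time spacing is permitted (and is the norm).
#'
#' @param times breath onset times in seconds, strictly increasing.
#' @param ve per-breath minute ventilation in L/min; all values `> 0`.
#' @param subject_id subject identifier.
#' @param label group label: `"PB"`, `"nPB"` or `"unknown"`.
#'
#' @return An object of class `breath_series`: a list with elements
#'   `subject_id`, `times`, `ve`, `label`.
#' @export
breath_series <- function(times, ve, subject_id = "s1",
                          label = c("unknown", "PB", "nPB")) {
  label <- match.arg(label)
  times <- as.numeric(times)
  ve <- as.numeric(ve)
  if (length(times) != length(ve))
    stop("times and ve must have equal length", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(ve)) || any(ve <= 0))
    stop("ve values must be finite and > 0", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 times = times, ve = ve, label = label),
            class = "breath_series")
}

#' @export
length.breath_series <- function(x) length(x$ve)

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %s [%s], %d breaths, %.1f-%.1f s, VE %.2f-%.2f L/min\n",
              x$subject_id, x$label, length(x$ve),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA,
              if (length(x$ve)) min(x$ve) else NA,
              if (length(x$ve)) max(x$ve) else NA))
  invisible(x)
}

# Respiratory rate r(t) in breaths/min: linear ramp rest->peak over the
# exercise phase, then linear return toward rest during recovery.
breath_rate_fun <- function(p) {
  function(t) {
    r <- ifelse(t <= p$exercise_duration,
                p$rest_rate + (p$peak_rate - p$rest_rate) *
                  t / p$exercise_duration,
                p$peak_rate - (p$peak_rate - p$rest_rate) *
                  pmin(1, (t - p$exercise_duration) /
                         max(p$recovery_duration, 1e-9)))
    pmax(r, 1e-6)
  }
}

# Clean VE trend in L/min: linear ramp ve_rest->ve_peak over exercise,
# then exponential decay toward ve_rest with time constant one third of
# the recovery phase.
ve_trend_fun <- function(p) {
  function(t) {
    tau <- max(p$recovery_duration / 3, 1e-9)
    ifelse(t <= p$exercise_duration,
           p$ve_rest + (p$ve_peak - p$ve_rest) * t / p$exercise_duration,
           p$ve_rest + (p$ve_peak - p$ve_rest) *
             exp(-(t - p$exercise_duration) / tau))
  }
}

# Breath onset times: invert the cumulative breath count
# N(t) = integral of r(s)/60 ds so that breath i occurs at N^{-1}(i).
# This keeps the total count within 1 of the integral of the rate.
breath_times_from_rate <- function(p) {
  total <- p$exercise_duration + p$recovery_duration
  grid <- seq(0, total, by = 0.01)
  rate <- breath_rate_fun(p)(grid) / 60        # breaths per second
  cum <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * diff(grid)))
  n_breaths <- floor(cum[length(cum)])
  stats::approx(cum, grid, xout = seq_len(n_breaths), ties = "ordered")$y
}

#' Generate one synthetic CPET ventilation recording
#'
#' Simulates a breath-by-breath VE series with the statistical structure
#' the downstream analysis assumes: a rising-then-falling ventilation
#' trend, an optional periodic-breathing amplitude modulation
#' `1 + m * sin(2*pi*t / pb_period + phi)`, multiplicative lognormal
#' measurement noise, and gasping artifacts in which a single breath is
#' recorded as two spuriously low breaths (each drawn uniformly in
#' `[0.2, 0.6]` of the local clean trend, hence always below the 0.8
#' threshold of the AR filter).
#'
#' @param params a [subject_params()] object.
#' @param subject_id identifier stored in the result.
#' @param label group label; by default inferred from `pb_amplitude`
#'   (`"PB"` if positive, else `"nPB"`).
#'
#' @return A [breath_series()] with attributes `gasp_indices` (integer
#'   indices, in the returned series, of artifact breaths),
#'   `clean_trend` (the noise-free local trend per returned breath) and
#'   `params`.
#' @examples
#' s <- generate_subject(subject_params(pb_amplitude = 0.4, seed = 7))
#' length(s)
#' @export
generate_subject <- function(params, subject_id = "sim1", label = NULL) {
  validate_subject_params(params)
  if (is.null(label))
    label <- if (params$pb_amplitude > 0) "PB" else "nPB"
  set.seed(params$seed)

  t <- breath_times_from_rate(params)
  trend <- ve_trend_fun(params)(t)
  phi <- stats::runif(1, 0, 2 * pi)
  modulation <- if (params$pb_amplitude > 0)
    1 + params$pb_amplitude * sin(2 * pi * t / params$pb_period + phi)
  else rep(1, length(t))
  noise <- if (params$noise_sigma > 0)
    exp(stats::rnorm(length(t), 0, params$noise_sigma))
  else rep(1, length(t))
  ve <- trend * modulation * noise

  is_gasp <- stats::runif(length(t)) < params$gasp_prob

  out_t <- vector("list", length(t))
  out_ve <- vector("list", length(t))
  out_trend <- vector("list", length(t))
  out_gasp <- vector("list", length(t))
  for (i in seq_along(t)) {
    if (is_gasp[i]) {
      # one gasping exhalation recorded as two low breaths; split the
      # inter-breath interval and draw each VE in [0.2, 0.6] x trend
      dt <- if (i < length(t)) (t[i + 1] - t[i]) else 60 / params$rest_rate
      tt <- c(t[i], t[i] + dt / 2 - 1e-4)
      vv <- stats::runif(2, 0.2, 0.6) * trend[i]
      out_t[[i]] <- tt
      out_ve[[i]] <- vv
      out_trend[[i]] <- rep(trend[i], 2)
      out_gasp[[i]] <- c(TRUE, TRUE)
    } else {
      out_t[[i]] <- t[i]
      out_ve[[i]] <- ve[i]
      out_trend[[i]] <- trend[i]
      out_gasp[[i]] <- FALSE
    }
  }
  times <- unlist(out_t)
  ves <- unlist(out_ve)
  series <- breath_series(times, ves, subject_id = subject_id,
                          label = label)
  attr(series, "gasp_indices") <- which(unlist(out_gasp))
  attr(series, "clean_trend") <- unlist(out_trend)
  attr(series, "params") <- params
  series
}

#' Generate a labeled PB / non-PB cohort
#'
#' Produces `n_pb` subjects with periodic-breathing modulation depth
#' drawn uniformly in `pb_range` and `n_npb` subjects with depth drawn
#' in `npb_range` (near zero).  PB cycle lengths are drawn uniformly in
#' `period_range`.  Per-subject seeds are derived deterministically from
#' the cohort seed, so a fixed seed regenerates the cohort exactly.
#'
#' @param n_pb,n_npb numbers of PB and non-PB subjects (>= 0).
#' @param base_params a [subject_params()] object supplying all fields
#'   other than `pb_amplitude`, `pb_period` and `seed`.
#' @param seed cohort-level RNG seed.
#' @param pb_range,npb_range modulation-depth ranges for the two groups.
#' @param period_range PB cycle-length range in seconds.
#'
#' @return A list of [breath_series()], PB subjects first.
#' @export
generate_cohort <- function(n_pb, n_npb, base_params = subject_params(),
                            seed = 1L,
                            pb_range = c(0.2, 0.5),
                            npb_range = c(0, 0.02),
                            period_range = c(40, 90)) {
  if (n_pb < 0 || n_npb < 0)
    stop("invalid parameter 'n_pb'/'n_npb': must be >= 0", call. = FALSE)
  validate_subject_params(base_params)
  n <- n_pb + n_npb
  if (n == 0L) return(list())
  set.seed(as.integer(seed))
  amp <- c(stats::runif(n_pb, pb_range[1], pb_range[2]),
           stats::runif(n_npb, npb_range[1], npb_range[2]))
  per <- stats::runif(n, period_range[1], period_range[2])
  # derived per-subject seeds, kept under 2^31
  sub_seed <- (as.integer(seed) %% 100000L) * 20011L + 7L * seq_len(n)
  lab <- rep(c("PB", "nPB"), c(n_pb, n_npb))
  ids <- c(sprintf("pb%04d", seq_len(n_pb)),
           sprintf("npb%04d", seq_len(n_npb)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base_params
    p$pb_amplitude <- amp[i]
    p$pb_period <- per[i]
    p$seed <- sub_seed[i]
    class(p) <- "subject_params"
    out[[i]] <- generate_subject(p, subject_id = ids[i], label = lab[i])
  }
  out
}
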