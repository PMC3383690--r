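#' Construct a validated current-trace record
#'
#' A `ts_record` holds a single-channel current time series in pA sampled at a
#' fixed interval. All downstream analysis (deconvolution, filter estimation,
#' event extraction) consumes this type.
#'
#' @param samples Numeric vector of current values (pA). Must be finite and
#'   non-empty.
#' @param dt Sampling interval in seconds (default 50 microseconds, the usual
#'   acquisition rate for the recordings this package targets).
#' @param t0 Start time of the first sample (s).
#' @param meta Optional named list of free-form annotations carried through
#'   unchanged.
#'
#' @return An object of class `ts_record`: a list with elements `samples`,
#'   `dt`, `t0` and `meta`.
#' @export
#' @examples
#' rec <- ts_record(c(1, -2, 0.5), dt = 5e-5)
#' length(rec$samples)
ts_record <- function(samples, dt = 5e-5, t0 = 0, meta = list()) {
  samples <- as.double(samples)
  if (length(samples) < 1L) {
    stop_data("record must contain at least one sample")
  }
  if (!all(is.finite(samples))) {
    stop_data("record contains non-finite samples (NaN/Inf)")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop_config("`dt` must be a single positive number (seconds)")
  }
  structure(
    list(samples = samples, dt = as.double(dt), t0 = as.double(t0),
         meta = as.list(meta)),
    class = "ts_record"
  )
}

#' @rdname ts_record
#' @param raw Numeric vector of raw samples to validate.
#' @export
validate_record <- function(raw, dt = 5e-5, t0 = 0, meta = list()) {
  ts_record(raw, dt = dt, t0 = t0, meta = meta)
}

#' @export
print.ts_record <- function(x, ...) {
  cat(sprintf(
    "<ts_record> %d samples, dt = %g s (%.4g s total), range [%.3g, %.3g] pA\n",
    length(x$samples), x$dt, length(x$samples) * x$dt,
    min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ts_record <- function(x) length(x$samples)

#' Additive-noise model for a recording
#'
#' Describes the additive Gaussian noise of a record: its standard deviation,
#' an optional autocorrelation time (single-pole / AR(1) spectrum), and whether
#' the likelihood should whiten residuals with the inverse noise spectrum.
#' Recording noise is rarely white; its correlation time is often comparable to
#' the EPSC decay, which is precisely what limits temporal resolution.
#' Whitening is therefore enabled by default; disabling it recovers a plain
#' white-noise likelihood.
#'
#' When `sigma` or `correlation_time` are `NULL` they are estimated from the
#' record at fit time (robust MAD estimate of the high-pass-filtered trace for
#' `sigma`; lag-1 autocorrelation of event-free stretches for the correlation
#' time).
#'
#' @param sigma Noise standard deviation (pA), or `NULL` to estimate.
#' @param correlation_time Noise autocorrelation time (s), or `NULL` to
#'   estimate when whitening is requested.
#' @param whitening Logical; whiten residuals by the inverse fitted AR(1)
#'   spectrum inside the likelihood.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma = NULL, correlation_time = NULL,
                        whitening = TRUE) {
  if (!is.null(sigma)) {
    if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
        sigma <= 0) {
      stop_config("`sigma` must be a single positive number (pA) or NULL")
    }
  }
  if (!is.null(correlation_time)) {
    if (!is.numeric(correlation_time) || length(correlation_time) != 1L ||
        !is.finite(correlation_time) || correlation_time <= 0) {
      stop_config("`correlation_time` must be a single positive number (s) or NULL")
    }
  }
  structure(
    list(sigma = sigma, correlation_time = correlation_time,
         whitening = isTRUE(whitening)),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> sigma = %s pA, correlation_time = %s s, whitening = %s\n",
              if (is.null(x$sigma)) "auto" else format(x$sigma),
              if (is.null(x$correlation_time)) "auto" else format(x$correlation_time),
              x$whitening))
  invisible(x)
}

# robust noise scale of the raw record (events are sparse; MAD ignores them)
estimate_sigma_raw <- function(x) {
  s <- mad(x, center = median(x))
  if (s <= 0) s <- sd(x)
  max(s, .Machine$double.eps)
}

# robust innovation scale after AR(1) differencing
estimate_sigma_innovation <- function(xw) {
  s <- mad(diff(xw)) / sqrt(2)
  if (s <= 0) s <- sd(diff(xw)) / sqrt(2)
  max(s, .Machine$double.eps)
}

# AR(1) coefficient of the noise, estimated from event-free stretches:
# samples within 3 robust SDs of the baseline.
estimate_ar1 <- function(x) {
  med <- median(x)
  s0 <- mad(x, center = med)
  if (s0 <= 0) return(0)
  keep <- abs(x - med) < 3 * s0
  ok <- keep[-1] & keep[-length(x)]
  x1 <- (x - med)[-length(x)][ok]
  x2 <- (x - med)[-1][ok]
  if (length(x1) < 10 || sum(x1^2) == 0) return(0)
  a <- sum(x1 * x2) / sum(x1^2)
  min(max(a, 0), 0.999)
}

# resolve a noise_model against a record: fill sigma/ar coefficient
resolve_noise <- function(record, noise) {
  x <- record$samples
  sigma_raw <- if (is.null(noise$sigma)) estimate_sigma_raw(x) else noise$sigma
  a <- 0
  if (noise$whitening) {
    a <- if (is.null(noise$correlation_time)) {
      estimate_ar1(x)
    } else {
      exp(-record$dt / noise$correlation_time)
    }
  }
  list(sigma_raw = sigma_raw, ar = a, whitening = noise$whitening)
}

#' Construct a dense deconvolved-signal estimate
#'
#' The deconvolved signal is a nonnegative mass per sample, in pA under the
#' peak-normalized filter convention: an isolated event of mass A produces a
#' current excursion with peak -A pA.
#'
#' @param values Nonnegative numeric vector (pA per sample).
#' @param dt Sampling interval (s).
#' @param default_level Default level m (> 0) of the maximum-entropy prior, in
#'   the same mass units.
#' @return An object of class `signal_estimate`.
#' @export
signal_estimate <- function(values, dt = 5e-5, default_level) {
  values <- as.double(values)
  if (any(!is.finite(values))) stop_domain("signal values must be finite")
  if (any(values < 0)) stop_domain("signal values must be nonnegative")
  if (!is.numeric(dt) || dt <= 0) stop_config("`dt` must be positive")
  if (!is.numeric(default_level) || length(default_level) != 1L ||
      default_level <= 0) {
    stop_domain("`default_level` must be a single positive number")
  }
  structure(
    list(values = values, dt = as.double(dt),
         default_level = as.double(default_level)),
    class = "signal_estimate"
  )
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat(sprintf("<signal_estimate> %d samples, dt = %g s, total mass %.4g pA, m = %g\n",
              length(x$values), x$dt, sum(x$values), x$default_level))
  invisible(x)
}

#' Construct and validate an event table
#'
#' The sparse representation of a record: one row per detected (or true)
#' release event. Times must be strictly increasing; amplitudes are negative
#' (inward currents) and `mass_pA = -amplitude_pA`.
#'
#' @param time_s Event times (s), strictly increasing.
#' @param amplitude_pA Signed event amplitudes (pA, all negative).
#' @param mass_pA Event masses (pA); defaults to `-amplitude_pA`.
#' @param n_samples Support width of each event in samples.
#' @return A tibble with class `event_table` prepended.
#' @export
event_table <- function(time_s = numeric(), amplitude_pA = numeric(),
                        mass_pA = -amplitude_pA,
                        n_samples = rep(NA_integer_, length(time_s))) {
  if (length(time_s)) {
    if (any(diff(time_s) <= 0)) stop_domain("event times must be strictly increasing")
    if (any(amplitude_pA >= 0)) stop_domain("event amplitudes must be negative")
  }
  out <- tibble(
    time_s = as.double(time_s),
    amplitude_pA = as.double(amplitude_pA),
    mass_pA = as.double(mass_pA),
    n_samples = as.integer(n_samples)
  )
  class(out) <- c("event_table", class(out))
  out
}

new_event_table <- function(df) {
  out <- as_tibble(df)
  class(out) <- c("event_table", class(out))
  out
}
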