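# Internal FFT convolution operator -------------------------------------
#
# The forward model is y[t] = sum_k f[k] s[t-k] (causal, zero-padded on the
# left). The likelihood optionally whitens residuals with the inverse AR(1)
# noise spectrum, which is equivalent to replacing the filter taps f by
# fw = f - a * shift(f) and the data x by x[t] - a x[t-1]. Both the forward
# map and its adjoint are applied by FFT on a padded grid.
#
# The "valid" region excludes the first length(fw) - 1 samples so that events
# preceding the record are never penalized.

new_conv_op <- function(taps, n, ar = 0) {
  fw <- if (ar > 0) c(taps, 0) - ar * c(0, taps) else taps
  lf <- length(fw)
  m <- nextn(n + lf, 2)
  Fh <- fft(c(fw, rep(0, m - lf)))
  list(Fh = Fh, m = m, n = n, lf = lf, fw = fw, kappa = sum(fw^2), ar = ar)
}

op_forward <- function(op, s) {
  Re(fft(op$Fh * fft(c(s, rep(0, op$m - op$n))), inverse = TRUE))[seq_len(op$n)] / op$m
}

# adjoint of the valid-region-restricted forward map; r must be zero on the
# excluded left edge
op_adjoint <- function(op, r) {
  Re(fft(Conj(op$Fh) * fft(c(r, rep(0, op$m - op$n))), inverse = TRUE))[seq_len(op$n)] / op$m
}

# whiten a record by AR(1) differencing (identity when ar = 0)
whiten_series <- function(x, ar) {
  if (ar <= 0) return(x)
  x - ar * c(0, x[-length(x)])
}

#' Forward convolution of a signal with an impulse response
#'
#' Applies the generative model: the observed (noise-free) current is the
#' causal convolution of the nonnegative release signal with the
#' everywhere-negative impulse response, `y[t] = sum_k f[k] s[t-k]`, with zero
#' padding at the left edge. Since s >= 0 and f <= 0, every output sample is
#' <= 0.
#'
#' @param signal A `signal_estimate` (or bare nonnegative numeric vector).
#' @param filter An `impulse_response`.
#' @param dt Sampling interval used when `signal` is a bare vector.
#' @return A `ts_record` of the same length as the signal.
#' @export
convolve_forward <- function(signal, filter, dt = NULL) {
  if (inherits(signal, "signal_estimate")) {
    s <- signal$values
    sdt <- signal$dt
  } else {
    s <- as.double(signal)
    if (any(s < 0)) stop_domain("signal values must be nonnegative")
    sdt <- dt %||% filter$dt
  }
  if (abs(sdt - filter$dt) > 1e-12) {
    stop_config("signal and filter sampling intervals differ")
  }
  op <- new_conv_op(filter$taps, length(s))
  y <- op_forward(op, s)
  y[y > 0] <- 0 # clip FFT round-off; exact result is <= 0
  ts_record(y, dt = sdt)
}

#' Sum of squared residuals of the convolution model
#'
#' Computes `sum((x - f * s)^2)` over the valid region (the first
#' `length(f) - 1` samples are excluded so unobserved pre-record events are
#' not penalized). With whitening enabled in the noise model, residuals are
#' first filtered by the inverse AR(1) noise spectrum.
#'
#' @param record A `ts_record`.
#' @param signal A `signal_estimate` or nonnegative numeric vector.
#' @param filter An `impulse_response`.
#' @param noise A `noise_model`; only the whitening settings are used here.
#' @return A single nonnegative number (pA^2).
#' @export
chi_squared <- function(record, signal, filter,
                        noise = noise_model(whitening = FALSE)) {
  s <- if (inherits(signal, "signal_estimate")) signal$values else as.double(signal)
  x <- record$samples
  if (length(s) != length(x)) stop_config("signal and record lengths differ")
  nz <- resolve_noise(record, noise)
  op <- new_conv_op(filter$taps, length(x), ar = nz$ar)
  xv <- whiten_series(x, nz$ar)
  r <- op_forward(op, s) - xv
  if (op$lf > 1) r[seq_len(op$lf - 1)] <- 0
  sum(r^2)
}
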