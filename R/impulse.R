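#' Empirical correlations between the record and a sparse signal
#'
#' The sign-constrained Wiener-Hopf estimate of the impulse response is built
#' from the cross-correlation of the data with the signal,
#' `C_xs[k] = sum_t x[t] s[t-k]` (lags `0 .. L_f - 1`, `t` restricted to the
#' valid region), and the autocorrelation of the signal,
#' `C_ss[d] = sum_t s[t] s[t+d]` (symmetric in `d`).
#'
#' @param record A `ts_record`.
#' @param signal A `signal_estimate` or numeric vector of the same length
#'   (typically the thresholded sparse representation).
#' @param n_taps Filter support length `L_f`.
#' @return A list of class `cross_correlations` with `C_xs` (length `n_taps`,
#'   lags 0..L_f-1) and `C_ss` (length `n_taps`, lags 0..L_f-1; symmetric).
#' @export
correlations <- function(record, signal, n_taps = 300L) {
  s <- if (inherits(signal, "signal_estimate")) signal$values else as.double(signal)
  x <- record$samples
  n <- length(x)
  if (length(s) != n) stop_config("signal length must equal record length")
  if (n_taps > n) stop_config("`n_taps` exceeds the record length")
  xv <- x
  if (n_taps > 1) xv[seq_len(n_taps - 1)] <- 0
  m <- nextn(n + n_taps, 2)
  S <- fft(c(s, rep(0, m - n)))
  X <- fft(c(xv, rep(0, m - n)))
  C_xs <- Re(fft(Conj(S) * X, inverse = TRUE))[seq_len(n_taps)] / m
  C_ss <- Re(fft(Conj(S) * S, inverse = TRUE))[seq_len(n_taps)] / m
  structure(list(C_xs = C_xs, C_ss = C_ss, n_taps = n_taps),
            class = "cross_correlations")
}

#' Solve the sign-constrained Wiener-Hopf equations for the filter
#'
#' Minimizes `||x - s * f||^2` subject to `f <= 0` elementwise: nonnegative
#' least squares on `-f` against the Toeplitz normal equations
#' `C_ss * f = C_xs` (Lawson-Hanson active set, smallest-index entering
#' variable). A small ridge (`1e-6 C_ss[0]`) conditions the Toeplitz form,
#' which is nearly singular between events for sparse signals. The result is
#' peak-normalized to `min(f) = -1`; the scale factor is returned so the
#' signal (and event masses) can be rescaled consistently.
#'
#' @param corr A `cross_correlations`.
#' @param dt Sampling interval for the returned filter (s).
#' @param ridge Relative ridge added to the Toeplitz diagonal.
#' @return A list with `filter` (an `impulse_response`) and `scale` (the
#'   factor by which the unnormalized solution exceeded the unit-peak
#'   convention; multiply signal masses by `scale` to keep `f * s` fixed).
#' @export
solve_filter <- function(corr, dt = 5e-5, ridge = 1e-6) {
  if (all(corr$C_xs == 0)) {
    stop_degenerate("all-zero cross-correlation: no events to learn the filter from")
  }
  Tm <- toeplitz(corr$C_ss)
  diag(Tm) <- diag(Tm) + ridge * corr$C_ss[1]
  R <- tryCatch(chol(Tm), error = function(e) {
    stop_numeric("signal autocorrelation is not positive definite")
  })
  d <- backsolve(R, -corr$C_xs, transpose = TRUE)
  g <- pracma::lsqnonneg(R, d)$x # g = -f >= 0
  f <- -g
  pk <- -min(f)
  if (pk <= 0) {
    stop_degenerate("constrained filter solution is identically zero")
  }
  list(filter = impulse_response(f / pk, dt = dt), scale = pk)
}
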