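#' Construct an EPSC impulse-response filter
#'
#' The impulse response is the stereotyped current waveform evoked by a single
#' release event. It is everywhere non-positive (EPSCs are inward currents)
#' and peak-normalized so that `min(taps) == -1`. Under this convention the
#' deconvolved mass of an isolated event equals the magnitude of its peak
#' current in pA, which makes event amplitudes directly comparable across
#' records.
#'
#' @param taps Numeric vector of filter taps, all `<= 0`.
#' @param dt Sampling interval (s).
#' @param normalize If `TRUE`, rescale so the most negative tap equals -1;
#'   if `FALSE`, `taps` must already satisfy `min(taps) == -1`.
#' @return An object of class `impulse_response` with elements `taps` and `dt`.
#' @export
#' @examples
#' f <- initial_filter_template(dt = 5e-5)
#' min(f$taps)  # -1 by convention
impulse_response <- function(taps, dt = 5e-5, normalize = FALSE) {
  taps <- as.double(taps)
  if (length(taps) < 1L) stop_config("filter must have at least one tap")
  if (!all(is.finite(taps))) stop_domain("filter taps must be finite")
  if (any(taps > 1e-12)) stop_domain("impulse response must be everywhere negative (taps <= 0)")
  taps[taps > 0] <- 0
  pk <- -min(taps)
  if (pk <= 0) stop_domain("filter must have at least one strictly negative tap")
  if (normalize) {
    taps <- taps / pk
  } else if (abs(pk - 1) > 1e-6) {
    stop_domain("filter must be peak-normalized (min(taps) == -1); use normalize = TRUE")
  }
  if (!is.numeric(dt) || dt <= 0) stop_config("`dt` must be positive")
  structure(list(taps = taps, dt = as.double(dt)), class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("<impulse_response> %d taps (%.3g ms), peak %.3g at tap %d\n",
              length(x$taps), length(x$taps) * x$dt * 1e3,
              min(x$taps), which.min(x$taps) - 1L))
  invisible(x)
}

#' @export
length.impulse_response <- function(x) length(x$taps)

#' Initial impulse-response template
#'
#' A difference-of-exponentials EPSC template: rise limited by the
#' postsynaptic membrane time constant and decay set by receptor reclosure,
#' `f(k) = -(1 - exp(-k dt / tau_rise)) * exp(-k dt / tau_decay)`,
#' peak-normalized. The default time constants (0.25 ms rise, 1 ms decay)
#' match typical AMPA-receptor EPSCs, whose reclosure is well approximated by
#' a single exponential with a 1-2 ms time constant. The blind loop uses this
#' template only as a starting point; the filter is re-estimated from the data.
#'
#' @param tau_rise Rise time constant (s).
#' @param tau_decay Decay time constant (s).
#' @param dt Sampling interval (s).
#' @param n_taps Filter support length in samples (default 300 taps = 15 ms at
#'   50 us: the ~0.25 ms rise plus ~10 decay constants).
#' @return An `impulse_response`.
#' @export
initial_filter_template <- function(tau_rise = 2.5e-4, tau_decay = 1e-3,
                                    dt = 5e-5, n_taps = 300L) {
  if (tau_rise <= 0 || tau_decay <= 0) stop_config("time constants must be positive")
  k <- seq_len(n_taps) - 1
  f <- -(1 - exp(-k * dt / tau_rise)) * exp(-k * dt / tau_decay)
  impulse_response(f, dt = dt, normalize = TRUE)
}

#' Align a filter's onset to tap zero
#'
#' Blind deconvolution only determines the filter and the event times up to a
#' common shift. This fixes the convention: the filter is rotated so that its
#' onset (the first tap reaching 5% of the peak) sits at tap 0, and all event
#' times are adjusted by the same shift, leaving the forward prediction
#' unchanged.
#'
#' @param filter An `impulse_response`.
#' @param events An `event_table` (optional) whose times are shifted to match.
#' @param onset_frac Onset threshold as a fraction of the peak.
#' @return A list with elements `filter`, `events` and `shift` (in taps;
#'   positive means the filter was advanced and event times grew by
#'   `shift * dt`).
#' @export
align_filter <- function(filter, events = NULL, onset_frac = 0.05) {
  f <- filter$taps
  k0 <- which(f <= -onset_frac)[1]
  shift <- k0 - 1L
  if (is.na(shift) || shift <= 0L) {
    return(list(filter = filter, events = events, shift = 0L))
  }
  f2 <- c(f[(shift + 1L):length(f)], rep(0, shift))
  out_f <- impulse_response(f2, dt = filter$dt, normalize = TRUE)
  out_e <- events
  if (!is.null(events) && nrow(events)) {
    out_e$time_s <- events$time_s + shift * filter$dt
  }
  list(filter = out_f, events = out_e, shift = shift)
}
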