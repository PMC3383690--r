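#' Linear (Gaussian-prior) deconvolution: the Wiener filter
#'
#' With the prior switched from entropic to Gaussian the MAP problem becomes
#' linear: minimize `chi^2(s) / (2 sigma^2) + (alpha / 2) sum((s - m)^2)`.
#' This is the classical Wiener solution; positivity is not enforced and the
#' result is not sparse. It serves as the non-blind fallback mode.
#'
#' The normal equations `(A'A / sigma^2 + alpha I) s = A'x / sigma^2 + alpha m`
#' are solved by conjugate gradients with the same FFT operator as the
#' entropic path. With `circular = TRUE` the operator wraps around (no valid
#' region), in which case the solution equals the closed-form spectral formula
#' `S(w) = conj(F(w)) X(w) / (|F(w)|^2 + alpha sigma^2)` (for `m = 0`).
#'
#' @inheritParams map_signal
#' @param circular Treat the record as circularly padded (spectral boundary
#'   conditions).
#' @param cg_tol,cg_max Conjugate-gradient stopping controls.
#' @return A `signal_estimate` (values may be negative).
#' @export
wiener_deconvolve <- function(record, filter, hyper = qme_hyperparameters(prior_kind = "gaussian"),
                              noise = noise_model(whitening = FALSE),
                              circular = FALSE, cg_tol = 1e-10, cg_max = 2000L) {
  if (hyper$prior_kind != "gaussian") {
    stop_config("wiener_deconvolve requires prior_kind = \"gaussian\"")
  }
  x <- record$samples
  n <- length(x)
  nz <- resolve_noise(record, noise)
  xv <- whiten_series(x, nz$ar)
  sigma <- hyper$sigma %||% estimate_sigma_innovation(xv)
  m <- hyper$m %||% 0
  alpha <- hyper$alpha
  sig2 <- sigma^2

  if (circular) {
    lf <- length(filter$taps)
    fw <- if (nz$ar > 0) c(filter$taps, 0) - nz$ar * c(0, filter$taps) else filter$taps
    Fh <- fft(c(fw, rep(0, n - length(fw))))
    X <- fft(xv)
    S <- (Conj(Fh) * X / sig2 + alpha * fft(rep(m, n))) / (Mod(Fh)^2 / sig2 + alpha)
    s <- Re(fft(S, inverse = TRUE)) / n
    return(structure(list(values = s, dt = record$dt, default_level = max(m, 1e-12)),
                     class = "signal_estimate"))
  }
  op <- new_conv_op(filter$taps, n, nz$ar)
  edge <- if (op$lf > 1) seq_len(op$lf - 1) else integer()
  Av <- function(v) {
    w <- op_forward(op, v)
    w[edge] <- 0
    op_adjoint(op, w) / sig2 + alpha * v
  }
  xe <- xv
  xe[edge] <- 0
  b <- op_adjoint(op, xe) / sig2 + alpha * m
  s <- rep(m, n)
  r <- b - Av(s)
  p <- r
  rs <- sum(r^2)
  b0 <- max(sqrt(sum(b^2)), .Machine$double.xmin)
  for (i in seq_len(cg_max)) {
    Ap <- Av(p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0) {
      stop_numeric("singular normal equations in the Wiener solve; increase alpha (ridge)")
    }
    a1 <- rs / pAp
    s <- s + a1 * p
    r <- r - a1 * Ap
    rs2 <- sum(r^2)
    if (sqrt(rs2) < cg_tol * b0) break
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  structure(list(values = s, dt = record$dt, default_level = max(m, 1e-12)),
            class = "signal_estimate")
}
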