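# Brute-force oracles and small fixtures shared across test files.

# nested-loop causal convolution: y[t] = sum_k f[k+1] s[t-k], zero-padded left
brute_convolve <- function(s, f) {
  n <- length(s)
  lf <- length(f)
  y <- numeric(n)
  for (t in seq_len(n)) {
    for (k in 0:(lf - 1)) {
      if (t - k >= 1) y[t] <- y[t] + f[k + 1] * s[t - k]
    }
  }
  y
}

# nested-loop chi-squared over the valid region
brute_chi2 <- function(x, s, f) {
  y <- brute_convolve(s, f)
  lf <- length(f)
  sum((x - y)[lf:length(x)]^2)
}

# nested-loop correlations matching correlations()
brute_correlations <- function(x, s, lf) {
  n <- length(x)
  xv <- x
  if (lf > 1) xv[seq_len(lf - 1)] <- 0
  C_xs <- numeric(lf)
  C_ss <- numeric(lf)
  for (k in 0:(lf - 1)) {
    for (t in seq_len(n - k)) {
      C_xs[k + 1] <- C_xs[k + 1] + s[t] * xv[t + k]
      C_ss[k + 1] <- C_ss[k + 1] + s[t] * s[t + k]
    }
  }
  list(C_xs = C_xs, C_ss = C_ss)
}

# exhaustive optimal assignment for event matching (<= 8 events):
# maximize number of matches within the window (ties by total |dt|)
brute_match_count <- function(tt, dd, window) {
  if (!length(tt) || !length(dd)) return(0L)
  best <- 0L
  nt <- length(tt)
  nd <- length(dd)
  # enumerate injective partial assignments recursively
  rec <- function(i, used, count) {
    best <<- max(best, count)
    if (i > nt) return()
    rec(i + 1L, used, count) # leave true event i unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && abs(tt[i] - dd[j]) <= window) {
        used[j] <- TRUE
        rec(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nd), 0L)
  best
}

# short test filter: 12-tap difference of exponentials, peak-normalized
tiny_filter <- function(dt = 5e-5, n_taps = 12L) {
  k <- seq_len(n_taps) - 1
  f <- -(1 - exp(-k / 2)) * exp(-k / 4)
  impulse_response(f, dt = dt, normalize = TRUE)
}

expect_tbl_rows <- function(tbl, n) {
  testthat::expect_equal(nrow(tbl), n)
}

# independent MAP oracle: exact dense damped Newton in log-space (direct
# solves; nothing shared with the package's truncated-CG/FFT path)
oracle_map_newton_u <- function(A, xv, alpha, m, maxit = 300L) {
  n <- ncol(A)
  K <- crossprod(A)
  b <- crossprod(A, xv)[, 1]
  phi <- function(u) {
    s <- exp(u)
    as.numeric(crossprod(s, K %*% s)) / 2 - sum(b * s) +
      alpha * sum(m - s + s * log(s / m))
  }
  u <- rep(log(m), n)
  val <- phi(u)
  for (it in seq_len(maxit)) {
    s <- exp(u)
    g_s <- (K %*% s)[, 1] - b + alpha * log(s / m)
    g_u <- s * g_s
    if (max(abs(g_u)) < 1e-12 * (1 + abs(val))) break
    H <- (s %o% s) * K
    diag(H) <- diag(H) + alpha * s + s * g_s
    lam <- 1e-10
    repeat {
      ch <- tryCatch(chol(H + lam * diag(n)), error = function(e) NULL)
      if (!is.null(ch)) break
      lam <- lam * 100
    }
    delta <- -backsolve(ch, backsolve(ch, g_u, transpose = TRUE))
    t <- 1
    repeat {
      un <- u + t * delta
      vn <- phi(un)
      if (vn <= val + 1e-4 * t * sum(g_u * delta) || t < 1e-14) break
      t <- t / 2
    }
    u <- un
    val <- vn
  }
  exp(u)
}
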