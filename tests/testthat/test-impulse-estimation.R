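test_that("correlations match the sifting property and the brute-force sums", {
  set.seed(21)
  f <- tiny_filter()
  n <- 60L
  lf <- 10L
  # unit delta: C_xs[k] = x[j + k]
  x <- rnorm(n)
  x[1:(lf - 1)] <- 0 # delta sits inside the valid region anyway
  s <- numeric(n)
  j <- 25L
  s[j] <- 1
  cc <- correlations(ts_record(x, dt = f$dt), s, n_taps = lf)
  expect_equal(cc$C_xs, x[j:(j + lf - 1)], tolerance = 1e-10)

  # zero signal: all correlations vanish
  cc0 <- correlations(ts_record(x, dt = f$dt), numeric(n), n_taps = lf)
  expect_true(all(cc0$C_xs == 0) && all(cc0$C_ss == 0))

  # random small vectors against nested loops
  x2 <- rnorm(n)
  s2 <- runif(n)
  cc2 <- correlations(ts_record(x2, dt = f$dt), s2, n_taps = lf)
  oracle <- brute_correlations(x2, s2, lf)
  expect_equal(cc2$C_xs, oracle$C_xs, tolerance = 1e-8)
  expect_equal(cc2$C_ss, oracle$C_ss, tolerance = 1e-8)

  expect_error(correlations(ts_record(x, dt = f$dt), s, n_taps = n + 1L),
               class = "epscdeconv_config_error")
})

test_that("noiseless sparse data give exact filter recovery", {
  f0 <- tiny_filter()
  n <- 400L
  s <- numeric(n)
  s[c(30, 120, 200, 310)] <- c(50, 80, 20, 60)
  x <- convolve_forward(s, f0, dt = f0$dt)
  cc <- correlations(x, s, n_taps = length(f0$taps))
  sol <- solve_filter(cc, dt = f0$dt)
  expect_lt(sqrt(mean((sol$filter$taps * sol$scale - f0$taps)^2)), 1e-6)
  expect_equal(sol$scale, 1, tolerance = 1e-6)
  # scale degeneracy: doubling the true filter halves nothing, scale doubles
  x2 <- ts_record(2 * x$samples, dt = f0$dt)
  sol2 <- solve_filter(correlations(x2, s, n_taps = length(f0$taps)),
                       dt = f0$dt)
  expect_equal(sol2$scale, 2, tolerance = 1e-6)
  expect_equal(sol2$filter$taps, f0$taps, tolerance = 1e-6)
})

test_that("a single unit delta reads the filter off the trace", {
  f0 <- tiny_filter()
  n <- 80L
  s <- numeric(n)
  s[30] <- 1 # far enough in that the response is fully observed
  x <- convolve_forward(s, f0, dt = f0$dt)
  sol <- solve_filter(correlations(x, s, n_taps = length(f0$taps)),
                      dt = f0$dt)
  expect_equal(sol$filter$taps * sol$scale, f0$taps, tolerance = 1e-6)
  expect_equal(sol$filter$taps * sol$scale, x$samples[30:41], tolerance = 1e-6)
})

test_that("negativity constraint matches a generic box-constrained solver", {
  # craft data whose unconstrained Wiener-Hopf solution has a positive lobe
  set.seed(23)
  lf <- 32L
  n <- 300L
  k <- 0:(lf - 1)
  f_pos <- -exp(-k / 4) + 0.35 * exp(-(k - 8)^2 / 4) # positive overshoot lobe
  s <- numeric(n)
  s[c(40, 110, 190, 260)] <- c(10, 25, 15, 30)
  x <- brute_convolve(s, f_pos) + rnorm(n, sd = 0.05)
  cc <- correlations(ts_record(x, dt = 5e-5), s, n_taps = lf)
  sol <- solve_filter(cc, dt = 5e-5)
  f_hat <- sol$filter$taps * sol$scale
  expect_true(all(f_hat <= 1e-10))

  # oracle: generic quadratic program min f'Tf/2 + c'f s.t. f <= 0 via
  # box-constrained BFGS
  Tm <- toeplitz(cc$C_ss)
  diag(Tm) <- diag(Tm) + 1e-6 * cc$C_ss[1]
  obj <- function(f) sum(f * (Tm %*% f)) / 2 - sum(cc$C_xs * f)
  grd <- function(f) (Tm %*% f)[, 1] - cc$C_xs
  o <- optim(rep(0, lf), obj, grd, method = "L-BFGS-B", upper = 0,
             lower = -Inf, control = list(maxit = 5000, factr = 1e1))
  expect_equal(f_hat, o$par, tolerance = 1e-5)

  # the constrained residual cannot beat the unconstrained one
  f_unc <- solve(Tm, cc$C_xs)
  expect_gte(obj(f_hat) + 1e-9, obj(f_unc))
})

test_that("degenerate correlations raise a classed error", {
  cc <- structure(list(C_xs = numeric(10), C_ss = c(1, rep(0, 9)),
                       n_taps = 10L), class = "cross_correlations")
  expect_error(solve_filter(cc), class = "epscdeconv_degenerate_filter_error")
})

test_that("filter re-estimation never increases the sparse-fit chi-squared", {
  set.seed(25)
  params <- ampa_params()
  g <- generate_poisson_record(rate = 60, duration = 0.35, seed = 31)
  rec <- g$record
  f <- initial_filter_template()
  sel <- select_alpha_sigma(rec, f, qme_hyperparameters(),
                            noise_model(correlation_time = 1e-3))
  ev <- epscdeconv:::extract_events_impl(
    sel$signal$values, 10 / sqrt(sum(f$taps^2)),
    k = 4, kmark = 1, gap = 2L, rsplit = 0.5, pad = 4L)
  expect_gt(nrow(ev), 5L)
  sp <- epscdeconv:::sparse_delta_signal(ev$pos, ev$mass, length(rec$samples))
  chi_before <- chi_squared(rec, sp, f)
  sol <- solve_filter(correlations(rec, sp, n_taps = length(f$taps)),
                      dt = rec$dt)
  chi_after <- chi_squared(rec, sp * sol$scale, sol$filter)
  expect_lte(chi_after, chi_before + 1e-6 * chi_before)
})

test_that("separable events give the amplitude-weighted isolated-waveform average", {
  # all events >= L_f apart: the Wiener-Hopf fit equals the least-squares
  # template of the isolated waveforms
  set.seed(27)
  f0 <- tiny_filter()
  lf <- length(f0$taps)
  n <- 500L
  pos <- c(50, 150, 280, 420)
  amp <- c(20, 45, 70, 35)
  s <- numeric(n)
  s[pos] <- amp
  # per-event stochastic waveforms: true filter plus event-specific wiggle
  x <- numeric(n)
  waves <- list()
  for (q in seq_along(pos)) {
    w <- f0$taps * (1 + rnorm(lf, sd = 0.05))
    w <- pmin(w, 0)
    waves[[q]] <- w
    x[pos[q]:(pos[q] + lf - 1)] <- x[pos[q]:(pos[q] + lf - 1)] + amp[q] * w
  }
  sol <- solve_filter(correlations(ts_record(x, dt = f0$dt), s, n_taps = lf),
                      dt = f0$dt)
  # oracle: the separable least squares reduce to the amplitude-weighted
  # (a^2 in the LS norm) average of the isolated event waveforms
  wavg <- Reduce(`+`, Map(function(w, a) a^2 * w, waves, amp)) / sum(amp^2)
  est <- sol$filter$taps * sol$scale
  expect_equal(est, pmin(wavg, 0), tolerance = 1e-6)
})

test_that("Toeplitz solve equals the dense normal-equation solve when unconstrained", {
  set.seed(29)
  f0 <- tiny_filter()
  n <- 200L
  s <- numeric(n)
  s[c(30, 90, 160)] <- c(5, 8, 3)
  x <- convolve_forward(s, f0, dt = f0$dt)$samples + rnorm(n, sd = 0.01)
  lf <- length(f0$taps)
  cc <- correlations(ts_record(x, dt = f0$dt), s, n_taps = lf)
  sol <- solve_filter(cc, dt = f0$dt)
  Tm <- toeplitz(cc$C_ss)
  diag(Tm) <- diag(Tm) + 1e-6 * cc$C_ss[1]
  dense <- solve(Tm, cc$C_xs)
  # the unconstrained solution is already negative here, so they coincide
  expect_true(all(dense <= 1e-8))
  expect_equal(sol$filter$taps * sol$scale, pmin(dense, 0), tolerance = 1e-6)
})

test_that("onset alignment is an identity on aligned filters and a pure shift otherwise", {
  f <- true_mean_filter() # onset-aligned: first tap already at 30% of peak
  al <- align_filter(f)
  expect_identical(al$shift, 0L)
  expect_equal(al$filter$taps, f$taps)

  # delay by 3 taps
  fd <- impulse_response(c(rep(0, 3), f$taps[1:(length(f$taps) - 3)]),
                         dt = f$dt, normalize = TRUE)
  ev <- event_table(time_s = c(0.01, 0.02), amplitude_pA = c(-30, -40))
  al2 <- align_filter(fd, ev)
  expect_identical(al2$shift, 3L)
  expect_equal(al2$events$time_s, ev$time_s + 3 * f$dt)
  # joint shift invariance of the forward model
  n <- 600L
  s <- numeric(n)
  s[200] <- 50
  y_before <- convolve_forward(s, fd, dt = f$dt)$samples
  s_shift <- numeric(n)
  s_shift[203] <- 50
  y_after <- convolve_forward(s_shift, al2$filter, dt = f$dt)$samples
  expect_equal(y_before[210:500], y_after[210:500], tolerance = 1e-10)
})

test_that("alignment preserves predictions under random delays", {
  set.seed(31)
  f <- true_mean_filter()
  n <- 800L
  for (d in sample(1:8, 3)) {
    fd <- impulse_response(c(rep(0, d), f$taps[1:(length(f$taps) - d)]),
                           dt = f$dt, normalize = TRUE)
    s <- numeric(n)
    idx <- sample(300:500, 4)
    s[idx] <- runif(4, 10, 60)
    al <- align_filter(fd)
    expect_identical(al$shift, as.integer(d))
    s2 <- numeric(n)
    s2[idx + d] <- s[idx]
    y1 <- convolve_forward(s, fd, dt = f$dt)$samples
    y2 <- convolve_forward(s2, al$filter, dt = f$dt)$samples
    expect_equal(y1[(300 + 10):(500 + 250)], y2[(300 + 10):(500 + 250)],
                 tolerance = 1e-9)
  }
})
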