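test_that("negentropy has its closed-form values and convexity floor", {
  expect_equal(negentropy(rep(2, 5), m = 2), 0)
  expect_equal(negentropy(0, m = 1), 1) # 0 log 0 limit: m - s
  expect_equal(negentropy(2, m = 1), 1 - 2 + 2 * log(2))
  expect_error(negentropy(c(-1), m = 1), class = "epscdeconv_domain_error")
  # H >= 0 on random nonnegative signals
  set.seed(1)
  for (i in 1:20) {
    s <- rexp(30)
    expect_gte(negentropy(s, m = runif(1, 0.1, 3)), 0)
  }
})

test_that("MAP solve of a zero record stays in (0, m] and obeys stationarity", {
  f <- tiny_filter()
  n <- 64L
  rec <- ts_record(numeric(n), dt = f$dt)
  hy <- qme_hyperparameters(alpha = 0.5, sigma = 1, m = 1, grad_tol = 1e-9,
                            max_newton_iters = 300L)
  fit <- map_signal(rec, f, hy, noise_model(whitening = FALSE))
  s <- fit$signal$values
  expect_true(all(s > 0))
  expect_true(all(s <= 1 + 1e-6))
  # per-element fixed-point oracle on the stationarity condition
  # alpha log(s_i/m) + (dchi2/ds_i)/(2 sigma^2) = 0, i.e. (x = 0, m = 1,
  # sigma = 1): s_i = exp(-(A'A s)_i / alpha), strongly damped Jacobi
  A <- epscdeconv:::dense_forward_matrix(f$taps, n)
  K <- crossprod(A)
  so <- rep(1, n)
  for (it in 1:100000) {
    target <- exp(-(K %*% so)[, 1] / 0.5)
    so_new <- so^0.95 * target^0.05
    if (max(abs(so_new - so)) < 1e-14) break
    so <- so_new
  }
  expect_lt(max(abs(0.5 * log(so) + (K %*% so)[, 1])), 1e-10) # oracle converged
  expect_lt(max(abs(s - so)), 1e-5)
})

test_that("a dominant prior pulls the signal to the default level", {
  set.seed(3)
  f <- tiny_filter()
  n <- 80L
  rec <- ts_record(rnorm(n), dt = f$dt)
  hy <- qme_hyperparameters(alpha = 1e8, sigma = 1, m = 0.5)
  fit <- map_signal(rec, f, hy, noise_model(whitening = FALSE))
  expect_equal(fit$signal$values, rep(0.5, n), tolerance = 1e-4)
})

test_that("noiseless event mass is recovered at small alpha", {
  f <- tiny_filter()
  n <- 120L
  s_true <- numeric(n)
  s_true[50] <- 100
  x <- convolve_forward(s_true, f, dt = f$dt)
  hy <- qme_hyperparameters(alpha = 1e-4, sigma = 1, m = 0.01)
  fit <- map_signal(x, f, hy, noise_model(whitening = FALSE))
  mass <- sum(fit$signal$values[40:60])
  expect_equal(mass, 100, tolerance = 0.01) # within 1 pA
})

test_that("MAP solution matches a generic constrained optimizer (N <= 128)", {
  set.seed(11)
  f <- tiny_filter()
  n <- 96L
  s_true <- numeric(n)
  s_true[c(25, 60)] <- c(40, 15)
  x <- convolve_forward(s_true, f, dt = f$dt)$samples + rnorm(n, sd = 1)
  rec <- ts_record(x, dt = f$dt)
  alpha <- 0.3
  m <- 0.05
  hy <- qme_hyperparameters(alpha = alpha, sigma = 1, m = m, grad_tol = 1e-9,
                            max_newton_iters = 200L)
  fit <- map_signal(rec, f, hy, noise_model(whitening = FALSE))
  # independent oracle: exact dense Newton in log-space
  A <- epscdeconv:::dense_forward_matrix(f$taps, n)
  xv <- x[length(f$taps):n]
  s_oracle <- oracle_map_newton_u(A, xv, alpha, m)
  expect_lt(max(abs(fit$signal$values - s_oracle)) / max(s_oracle), 1e-6)
  # optimizer sanity: solution no worse than the truth or the default level
  obj <- function(s) {
    r <- A %*% s - xv
    sum(r^2) / 2 + alpha * sum(m - s + s * log(s / m))
  }
  expect_lte(obj(fit$signal$values), obj(rep(m, n)) + 1e-8)
  expect_lte(obj(fit$signal$values), obj(pmax(s_true, 1e-12)) + 1e-8)
})

test_that("Wiener mode equals the closed-form spectral solution on circular data", {
  set.seed(5)
  f <- tiny_filter()
  n <- 128L
  x <- rnorm(n)
  rec <- ts_record(x, dt = f$dt)
  alpha <- 0.7
  sigma <- 1.3
  hy <- qme_hyperparameters(alpha = alpha, sigma = sigma, m = NULL,
                            prior_kind = "gaussian")
  hy$m <- 0
  sol <- wiener_deconvolve(rec, f, hy, noise_model(whitening = FALSE),
                           circular = TRUE)
  Fh <- fft(c(f$taps, rep(0, n - length(f$taps))))
  oracle <- Re(fft(Conj(Fh) * fft(x) / (Mod(Fh)^2 + alpha * sigma^2),
                   inverse = TRUE)) / n
  expect_equal(sol$values, oracle, tolerance = 1e-8)
})

test_that("Wiener limits: alpha -> 0 fits exactly, alpha -> Inf returns m", {
  set.seed(6)
  f <- tiny_filter()
  n <- 100L
  s_true <- pmax(rnorm(n), 0)
  x <- convolve_forward(s_true, f, dt = f$dt)
  hy0 <- qme_hyperparameters(alpha = 1e-10, sigma = 1, prior_kind = "gaussian")
  hy0$m <- 0
  s0 <- wiener_deconvolve(x, f, hy0, noise_model(whitening = FALSE))
  expect_lt(chi_squared(x, s0$values, f) / max(sum(x$samples^2), 1), 1e-6)
  hyI <- qme_hyperparameters(alpha = 1e10, sigma = 1, prior_kind = "gaussian")
  hyI$m <- 0.4
  sI <- wiener_deconvolve(x, f, hyI, noise_model(whitening = FALSE))
  expect_equal(sI$values, rep(0.4, n), tolerance = 1e-4)
  expect_error(
    wiener_deconvolve(x, f, qme_hyperparameters(prior_kind = "qme")),
    class = "epscdeconv_config_error")
})

test_that("good-measurement estimators agree across methods", {
  set.seed(9)
  f <- tiny_filter()
  n <- 600L
  s <- rep(0.05, n)
  s[c(100, 101, 300, 450)] <- c(30, 10, 80, 5)
  sig <- signal_estimate(s, dt = f$dt, default_level = 0.05)
  nz <- noise_model(sigma = 2, correlation_time = 1e-3, whitening = FALSE)
  for (alpha in c(0.05, 0.5, 5)) {
    gd <- good_measurements(sig, f, alpha, 2, nz, method = "dense")
    gb <- good_measurements(sig, f, alpha, 2, nz, method = "blocks")
    gh <- good_measurements(sig, f, alpha, 2, nz, method = "hutchinson",
                            n_probes = 64L, seed = 2)
    expect_gte(gd, 0)
    expect_lte(gd, n - length(f$taps) + 1)
    expect_equal(gb, gd, tolerance = 0.05)
    # Hutchinson is Monte Carlo: generous tolerance
    expect_equal(gh, gd, tolerance = 0.15)
  }
})

test_that("evidence selection recovers the noise scale with one strong event", {
  set.seed(13)
  f <- initial_filter_template()
  n <- 4000L
  s_true <- numeric(n)
  s_true[2000] <- 100
  clean <- convolve_forward(s_true, f, dt = f$dt)$samples
  nz_p <- noise_params(rms = 10, correlation_time = 1e-3, seed = 21)
  x <- clean + colored_noise(n, nz_p, dt = f$dt)$samples
  rec <- ts_record(x, dt = f$dt)
  sel <- select_alpha_sigma(rec, f, qme_hyperparameters(),
                            noise_model(correlation_time = 1e-3))
  # sigma here is the innovation scale of the AR(1) noise model
  a <- exp(-f$dt / 1e-3)
  sigma_true <- 10 * sqrt(1 - a^2)
  expect_lt(abs(sel$hyper$sigma - sigma_true) / sigma_true, 0.2)
  expect_gte(sel$diagnostics$G, 0)
  expect_lt(sel$diagnostics$G, (n - length(f$taps) + 1) / 10) # sparse record
})

test_that("pure-noise records produce no events under evidence selection", {
  f <- initial_filter_template()
  n <- 2500L
  hits <- 0L
  runs <- 10L
  for (k in seq_len(runs)) {
    x <- colored_noise(n, noise_params(rms = 10, seed = 100 + k), dt = f$dt)
    rec <- ts_record(x$samples, dt = f$dt)
    sel <- select_alpha_sigma(rec, f, qme_hyperparameters(),
                              noise_model(correlation_time = 1e-3))
    ev <- extract_events(sel$signal, f, 10, blind_config())
    if (nrow(ev) == 0L) hits <- hits + 1L
  }
  expect_gte(hits, runs - 1L) # >= 90% of seeded runs event-free
})

test_that("the evidence curve is unimodal with a single event and handles a 1-point grid", {
  set.seed(15)
  f <- tiny_filter()
  n <- 400L
  s_true <- numeric(n)
  s_true[200] <- 60
  x <- convolve_forward(s_true, f, dt = f$dt)$samples + rnorm(n, sd = 2)
  rec <- ts_record(x, dt = f$dt)
  hy <- qme_hyperparameters(sigma = 2, m = 0.05)
  grid <- 10^seq(-4, 0, length.out = 9)
  curve <- evidence_curve(rec, f, hy, noise_model(whitening = FALSE), grid)
  expect_equal(nrow(curve), 9L)
  lz <- curve$log_evidence
  pk <- which.max(lz)
  # no secondary maxima: increasing up to the peak, decreasing after
  expect_true(all(diff(lz[seq_len(pk)]) > 0 | abs(diff(lz[seq_len(pk)])) < 1e-6))
  expect_true(all(diff(lz[pk:length(lz)]) < 0 |
                    abs(diff(lz[pk:length(lz)])) < 1e-6))
  one <- evidence_curve(rec, f, hy, noise_model(whitening = FALSE), grid[3])
  expect_equal(nrow(one), 1L)
  expect_equal(one$log_evidence, curve$log_evidence[3], tolerance = 1e-4)
})

test_that("fixed-alpha and fixed-sigma flags suppress the updates", {
  set.seed(17)
  f <- tiny_filter()
  n <- 300L
  x <- rnorm(n, sd = 2)
  rec <- ts_record(x, dt = f$dt)
  hy <- qme_hyperparameters(alpha = 0.7, sigma = 2.5, m = 0.05,
                            alpha_fixed = TRUE, sigma_fixed = TRUE)
  sel <- select_alpha_sigma(rec, f, hy, noise_model(whitening = FALSE))
  expect_identical(sel$hyper$alpha, 0.7)
  expect_identical(sel$hyper$sigma, 2.5)
})
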