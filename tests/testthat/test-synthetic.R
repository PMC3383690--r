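test_that("a closed-channel start yields an all-zero EPSC and bounds are enforced", {
  p <- ampa_params()
  rec <- simulate_epsc(p, n_open0 = 0, duration = 0.01, seed = 1)
  expect_true(all(rec$samples == 0))
  expect_error(simulate_epsc(p, n_open0 = 151), class = "epscdeconv_domain_error")
})

test_that("mean open count decays as binomial thinning predicts", {
  p <- ampa_params()
  n0 <- 60L
  steps <- 40L
  reps <- 2000L
  cnt <- withr::with_seed(5, epscdeconv:::sim_open_counts(rep(n0, reps), steps, p))
  for (t in c(10L, 20L, 40L)) {
    expected <- n0 * exp(-(t - 1) * p$dt / p$tau_close)
    ps <- exp(-(t - 1) * p$dt / p$tau_close)
    se <- sqrt(n0 * ps * (1 - ps) / reps)
    expect_lt(abs(mean(cnt[t, ]) - expected), 3 * max(se, 1e-6))
  }
})

test_that("the filtered peak matches a high-resolution ODE oracle", {
  p <- ampa_params()
  # oracle: integrate dy/dt = (u - y)/tau_m with u = exp(-t/tau_close) at
  # 100x finer resolution, take the peak
  fine <- p$dt / 100
  tt <- seq(0, 12 * p$tau_close, by = fine)
  u <- exp(-tt / p$tau_close)
  y <- 0
  pk <- 0
  for (i in seq_along(tt)) {
    y <- y + fine * (u[i] - y) / p$tau_membrane
    pk <- max(pk, y)
  }
  # the generator's first-order filter update carries O(dt/tau_m) bias
  # relative to the continuous limit; 50 us at 0.25 ms is ~6%
  P_d <- peak_response_factor(p)
  expect_equal(P_d, pk, tolerance = 0.08)

  # ensemble peaks of stochastic EPSCs agree within Monte-Carlo error
  n0 <- 60L
  reps <- 300L
  peaks <- withr::with_seed(7, vapply(seq_len(reps), function(i) {
    min(simulate_epsc(p, n0, duration = 0.012)$samples)
  }, numeric(1)))
  expect_lt(abs(mean(-peaks) - n0 * p$i_channel * P_d) /
              (n0 * p$i_channel * P_d), 0.05)
})

test_that("colored noise hits its RMS exactly and decorrelates as an OU process", {
  nz <- colored_noise(1e5, noise_params(rms = 10, seed = 3), dt = 5e-5)
  expect_equal(sqrt(mean(nz$samples^2)), 10, tolerance = 1e-12)
  # lag of one correlation time: autocorrelation e^-1
  lag <- round(1e-3 / 5e-5)
  x <- nz$samples
  ac <- mean(x[-(1:lag)] * x[1:(length(x) - lag)]) / mean(x^2)
  expect_equal(ac, exp(-1), tolerance = 0.05)
  z <- colored_noise(100, noise_params(rms = 0), dt = 5e-5)
  expect_true(all(z$samples == 0))
})

test_that("Poisson records have the right event counts and conserve their truth", {
  g0 <- generate_poisson_record(rate = 0, duration = 0.05, seed = 1)
  expect_equal(nrow(g0$truth), 0L)
  expect_length(g0$record$samples, round(0.05 / 5e-5))

  counts <- vapply(1:60, function(k) {
    nrow(generate_poisson_record(rate = 40, duration = 0.25, seed = k,
                                 noise = noise_params(rms = 0))$truth)
  }, numeric(1))
  lambda <- 40 * 0.25
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 60))

  # truth conservation: noiseless record rebuilt from truth + mean kinetics
  # reproduces the stored peaks within the channel-stochasticity spread
  g <- generate_poisson_record(rate = 15, duration = 0.4, seed = 9,
                               noise = noise_params(rms = 0))
  f_true <- true_mean_filter()
  n <- length(g$record$samples)
  idx <- round(g$truth$time_s / 5e-5) + 1
  s <- numeric(n)
  s[idx] <- -g$truth$true_amplitude_pA
  rebuilt <- convolve_forward(s, f_true, dt = 5e-5)$samples
  for (j in seq_len(nrow(g$truth))) {
    win <- idx[j]:min(n, idx[j] + 40)
    expect_lt(abs(min(g$record$samples[win]) - min(rebuilt[win])),
              0.35 * abs(g$truth$true_amplitude_pA[j]) + 3)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_poisson_record(rate = 30, duration = 0.2, seed = 42)
  b <- generate_poisson_record(rate = 30, duration = 0.2, seed = 42)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth, b$truth)
  p1 <- generate_pairs_assay(separations = 2.5e-4, n_trials = 3, seed = 7)
  p2 <- generate_pairs_assay(separations = 2.5e-4, n_trials = 3, seed = 7)
  expect_identical(p1[[2]]$record$samples, p2[[2]]$record$samples)
})

test_that("the pairs assay provides the stated separations and layout", {
  trials <- generate_pairs_assay(n_trials = 2, seed = 11)
  seps <- unique(vapply(trials, function(tr) tr$separation_s, numeric(1)))
  expect_true(2.5e-4 %in% seps) # 250 us = 5 samples at 50 us
  tr <- trials[[1]]
  expect_equal(nrow(tr$truth), 2L)
  expect_equal(diff(tr$truth$time_s), tr$separation_s, tolerance = 5e-5 / 2)
  # generous flanks: first event well after the filter support
  expect_gt(tr$truth$time_s[1], 0.015)
  expect_equal(generate_pairs_assay(n_trials = 0), list())
})

test_that("the amplitude assay hits its target peaks in expectation", {
  expect_error(generate_amplitude_assay(amplitudes = c(-5, 3)),
               class = "epscdeconv_domain_error")
  sweep <- generate_amplitude_assay(n_trials = 1, seed = 1)
  tgts <- vapply(sweep, function(tr) tr$target_pA, numeric(1))
  expect_equal(min(tgts), -30)
  expect_equal(max(tgts), -1)

  # noiseless -30 pA: trace minimum within the channel-stochasticity spread
  trials <- generate_amplitude_assay(amplitudes = -30, n_trials = 80,
                                     noise = noise_params(rms = 0), seed = 13)
  mins <- vapply(trials, function(tr) min(tr$record$samples), numeric(1))
  expect_lt(abs(mean(mins) + 30), 1.5) # mean of peaks ~ target
  # per-trial truth equals the conditional expectation given the draw
  tr <- trials[[1]]
  expect_lt(abs(min(tr$record$samples) - tr$truth$true_amplitude_pA), 6)
})

test_that("multiquantal stages follow their distributions", {
  # forced q = 1 at quantum 0.1: binomial mean 15 channels
  st1 <- generate_multiquantal(1, n_events = 4000, mean_quanta = 1, seed = 3)
  expect_true(all(st1$q == 1L))
  se <- sqrt(150 * 0.1 * 0.9 / 4000)
  expect_lt(abs(mean(st1$amplitudes) - 15), 3 * se)

  # preset A: mean quanta 4 -> mean open ~ 150 * min(q * 0.1, 1)
  stA <- generate_multiquantal(1, n_events = 4000, seed = 5)
  expect_equal(mean(stA$q), 4, tolerance = 0.1)

  # preset B geometry: 300 receptors, quantum 0.125 = 37.5 channels
  stB <- generate_multiquantal(1, n_events = 3000, n_receptors = 300,
                               quantum_fraction = 0.125, mean_quanta = 1,
                               seed = 6)
  expect_lt(abs(mean(stB$amplitudes) - 37.5), 3 * sqrt(300 * 0.125 * 0.875 / 3000))

  # stage 2 blurs but preserves scale via the peak factor
  st2 <- generate_multiquantal(2, n_events = 400, mean_quanta = 1, seed = 7)
  pf <- peak_response_factor()
  expect_equal(mean(st2$amplitudes), 15 * pf, tolerance = 0.1 * 15 * pf)

  # stage 3 returns a record + truth
  st3 <- generate_multiquantal(3, n_events = 50, rate = 50, seed = 8)
  expect_s3_class(st3$record, "ts_record")
  expect_equal(nrow(st3$truth), 50L)
  expect_error(generate_multiquantal(4), class = "epscdeconv_config_error")
})

test_that("the complex preset produces gamma amplitudes and exponential intervals", {
  g <- generate_complex_record(n_events = 400, rate = 100, seed = 17)
  expect_gt(nrow(g$truth), 300)
  iv <- diff(g$truth$time_s)
  # exponential MLE rate within sampling error of the nominal rate
  expect_lt(abs(1 / mean(iv) - 100) / 100, 3 / sqrt(length(iv)) + 0.1)
  amp <- abs(g$truth$true_amplitude_pA)
  expect_gt(mean(amp), 20)
  expect_lt(mean(amp), 60)
})
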