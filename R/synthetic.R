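#' Parameters of the stochastic AMPA-receptor EPSC generator
#'
#' Synthetic EPSCs are generated by opening a number of receptor channels
#' instantaneously, letting each reclose independently with an exponential
#' lifetime, and low-pass filtering the summed channel current with the
#' postsynaptic membrane time constant. Defaults follow typical hair-cell
#' synapse recordings: 150 receptors, ~1 ms reclosure, 0.25 ms membrane
#' filter, 50 us sampling.
#'
#' @param n_receptors Total receptor count.
#' @param i_channel Single-channel current (pA).
#' @param tau_close Reclosure time constant (s).
#' @param tau_membrane Membrane low-pass time constant (s).
#' @param dt Sampling interval (s).
#' @return An object of class `ampa_params`.
#' @export
ampa_params <- function(n_receptors = 150L, i_channel = 1.0,
                        tau_close = 1e-3, tau_membrane = 0.25e-3,
                        dt = 5e-5) {
  if (n_receptors < 1L) stop_domain("`n_receptors` must be >= 1")
  if (i_channel <= 0 || tau_close <= 0 || tau_membrane <= 0 || dt <= 0) {
    stop_config("all generator parameters must be positive")
  }
  structure(
    list(n_receptors = as.integer(n_receptors), i_channel = i_channel,
         tau_close = tau_close, tau_membrane = tau_membrane, dt = dt),
    class = "ampa_params"
  )
}

#' Parameters of the additive colored noise
#'
#' White Gaussian noise passed through a single-pole low-pass (an AR(1) /
#' Ornstein-Uhlenbeck process) and rescaled to an exact empirical RMS.
#' The default 1 ms correlation time is comparable to the EPSC decay, which
#' is what makes event detection hard.
#'
#' @param rms Root-mean-square amplitude (pA); 0 gives a zero trace.
#' @param correlation_time Autocorrelation time (s).
#' @param seed Optional seed for reproducibility.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(rms = 10, correlation_time = 1e-3, seed = NULL) {
  if (rms < 0) stop_config("`rms` must be >= 0")
  if (correlation_time <= 0) stop_config("`correlation_time` must be positive")
  structure(list(rms = rms, correlation_time = correlation_time, seed = seed),
            class = "noise_params")
}

# discrete RC low-pass used throughout: y <- y + (dt/tau)(u - y)
rc_lowpass <- function(u, dt, tau) {
  a <- dt / tau
  as.numeric(stats::filter(u * a, 1 - a, method = "recursive"))
}

#' Expected peak of the filtered unit-channel response
#'
#' The expected open count after an instantaneous opening decays as
#' `exp(-t / tau_close)`; filtering by the membrane RC gives the expected
#' waveform whose peak (per open channel, per unit single-channel current)
#' this returns. Used to convert between open-channel counts and expected
#' peak current: `peak = i_channel * n_open * peak_response_factor(params)`.
#'
#' @param params An `ampa_params`.
#' @return A single positive number.
#' @export
peak_response_factor <- function(params = ampa_params()) {
  n <- ceiling(12 * params$tau_close / params$dt)
  k <- seq_len(n) - 1
  max(rc_lowpass(exp(-k * params$dt / params$tau_close), params$dt,
                 params$tau_membrane))
}

#' True mean-kinetics impulse response of the generator
#'
#' The ideal EPSC filter: low-pass filtered mean receptor kinetics, sampled at
#' the generator's `dt` and peak-normalized. This is the ground-truth filter
#' the blind loop should recover.
#'
#' @param params An `ampa_params`.
#' @param n_taps Support length.
#' @return An `impulse_response`.
#' @export
true_mean_filter <- function(params = ampa_params(), n_taps = 300L) {
  k <- seq_len(n_taps) - 1
  y <- rc_lowpass(exp(-k * params$dt / params$tau_close), params$dt,
                  params$tau_membrane)
  impulse_response(-y, dt = params$dt, normalize = TRUE)
}

# vectorized reclosure: one column per event, rows are time steps
sim_open_counts <- function(n_open0, n_steps, params) {
  ne <- length(n_open0)
  out <- matrix(0L, n_steps, ne)
  cur <- as.integer(n_open0)
  pk <- exp(-params$dt / params$tau_close)
  for (t in seq_len(n_steps)) {
    out[t, ] <- cur
    alive <- cur > 0L
    if (any(alive)) cur[alive] <- rbinom(sum(alive), cur[alive], pk)
  }
  out
}

#' Simulate a single stochastic EPSC
#'
#' `n_open0` channels open instantaneously at t = 0, each recloses
#' independently with exponential lifetime `tau_close`; the summed channel
#' current (`-i_channel` per open channel) is low-pass filtered by the
#' membrane time constant.
#'
#' @param params An `ampa_params`.
#' @param n_open0 Initially open channel count (0..n_receptors).
#' @param duration Record duration (s).
#' @param seed Optional seed.
#' @return A `ts_record` of the noiseless EPSC.
#' @export
simulate_epsc <- function(params = ampa_params(), n_open0, duration = 0.02,
                          seed = NULL) {
  if (n_open0 < 0 || n_open0 > params$n_receptors) {
    stop_domain("`n_open0` must lie in [0, n_receptors]")
  }
  n <- max(1L, round(duration / params$dt))
  run <- function() {
    cnt <- sim_open_counts(n_open0, n, params)[, 1]
    rc_lowpass(-params$i_channel * cnt, params$dt, params$tau_membrane)
  }
  y <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ts_record(y, dt = params$dt)
}

#' Colored Gaussian noise trace
#'
#' White Gaussian noise filtered by a single-pole low-pass with the given
#' correlation time, then rescaled so the empirical RMS equals `params$rms`
#' exactly.
#'
#' @param n_samples Number of samples.
#' @param params A `noise_params`.
#' @param dt Sampling interval (s).
#' @return A `ts_record`.
#' @export
colored_noise <- function(n_samples, params = noise_params(), dt = 5e-5) {
  run <- function() {
    if (params$rms == 0) return(numeric(n_samples))
    a <- exp(-dt / params$correlation_time)
    z <- as.numeric(stats::filter(rnorm(n_samples), a, method = "recursive"))
    z * params$rms / sqrt(mean(z^2))
  }
  y <- if (is.null(params$seed)) run() else withr::with_seed(params$seed, run())
  ts_record(y, dt = dt)
}

# place events (sample indices, open counts) into a record and filter+noise it
assemble_record <- function(ev_idx, n_open0, n_samples, params, noise_p,
                            i_channel = params$i_channel) {
  support <- ceiling(12 * params$tau_close / params$dt)
  u <- numeric(n_samples + support)
  if (length(ev_idx)) {
    cnts <- sim_open_counts(n_open0, support, params)
    for (j in seq_along(ev_idx)) {
      ix <- ev_idx[j]:(ev_idx[j] + support - 1L)
      u[ix] <- u[ix] - i_channel * cnts[, j]
    }
  }
  clean <- rc_lowpass(u, params$dt, params$tau_membrane)[seq_len(n_samples)]
  nz <- colored_noise(n_samples, noise_params(noise_p$rms,
                                              noise_p$correlation_time),
                      dt = params$dt)
  list(record = ts_record(clean + nz$samples, dt = params$dt),
       clean = clean)
}

#' Ground-truthed Poisson record of stochastic EPSCs
#'
#' Event times follow a Poisson process; at each event a fraction of the
#' receptor pool opens (binomial draw at a sampled open fraction), recloses
#' stochastically, and the summed current is membrane-filtered; colored noise
#' is added. The ground truth records, per event, the time, initially open
#' channel count, and the expected filtered peak amplitude
#' (`-i_channel * n_open0 * peak_response_factor`).
#'
#' @param rate Event rate (events/s).
#' @param duration Record duration (s).
#' @param amplitude_sampler Function `n -> open fractions in (0, 1]`; default
#'   uniform on `[0.1, 0.5]`.
#' @param params An `ampa_params`.
#' @param noise A `noise_params`.
#' @param seed Optional seed.
#' @param i_channel Override of the single-channel current (pA).
#' @return A list with `record` (a `ts_record`) and `truth` (a tibble with
#'   `time_s`, `true_amplitude_pA`, `n_open0`, `q`), plus the generator
#'   settings as attributes.
#' @export
generate_poisson_record <- function(rate, duration,
                                    amplitude_sampler = function(n) runif(n, 0.1, 0.5),
                                    params = ampa_params(),
                                    noise = noise_params(), seed = NULL,
                                    i_channel = params$i_channel) {
  if (rate < 0 || duration <= 0) stop_config("`rate` >= 0 and `duration` > 0 required")
  run <- function() {
    n <- round(duration / params$dt)
    n_ev <- rpois(1, rate * duration)
    pf <- peak_response_factor(params)
    if (n_ev == 0) {
      rec <- assemble_record(integer(), integer(), n, params, noise, i_channel)
      return(list(record = rec$record,
                  truth = tibble(time_s = numeric(), true_amplitude_pA = numeric(),
                                 n_open0 = integer(), q = integer())))
    }
    idx <- sort(sample.int(n, n_ev, replace = TRUE))
    p <- amplitude_sampler(n_ev)
    n0 <- rbinom(n_ev, params$n_receptors, pmin(pmax(p, 0), 1))
    rec <- assemble_record(idx, n0, n, params, noise, i_channel)
    list(record = rec$record,
         truth = tibble(time_s = (idx - 1) * params$dt,
                        true_amplitude_pA = -i_channel * n0 * pf,
                        n_open0 = as.integer(n0),
                        q = rep(NA_integer_, n_ev)))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "params") <- params
  attr(out, "noise") <- noise
  attr(out, "seed") <- seed
  out
}

#' Complex-record preset
#'
#' A long record of overlapping EPSCs with exponentially distributed
#' inter-event intervals and gamma-distributed peak amplitudes, emulating
#' spontaneous release at a high-rate synapse. The full-scale preset holds
#' 3968 events; `n_events` scales it down for desk-size runs.
#'
#' @param n_events Expected event count.
#' @param rate Event rate (events/s).
#' @param gamma_shape,gamma_mean Shape and mean (pA, magnitude) of the
#'   amplitude distribution.
#' @inheritParams generate_poisson_record
#' @return As [generate_poisson_record()].
#' @export
generate_complex_record <- function(n_events = 3968, rate = 100,
                                    gamma_shape = 3, gamma_mean = 40,
                                    params = ampa_params(),
                                    noise = noise_params(), seed = NULL) {
  pf <- peak_response_factor(params)
  amax <- params$n_receptors * params$i_channel * pf
  sampler <- function(n) {
    a <- rgamma(n, shape = gamma_shape, scale = gamma_mean / gamma_shape)
    pmin(pmax(a / amax, 1 / params$n_receptors), 1)
  }
  generate_poisson_record(rate = rate, duration = n_events / rate,
                          amplitude_sampler = sampler, params = params,
                          noise = noise, seed = seed)
}

# shared helper for windowed assay trials: one event set per fixed-length
# window, generous quiet flanks
build_trial <- function(ev_offsets, n_open0, wlen, params, noise, i_channel) {
  rec <- assemble_record(ev_offsets, n_open0, wlen, params, noise, i_channel)
  pf <- peak_response_factor(params)
  list(record = rec$record,
       truth = tibble(time_s = (ev_offsets - 1) * params$dt,
                      true_amplitude_pA = -i_channel * n_open0 * pf,
                      n_open0 = as.integer(n_open0),
                      q = rep(NA_integer_, length(ev_offsets))))
}

#' Paired-EPSC temporal-resolution assay
#'
#' Per trial, two unitary EPSCs of matched nominal amplitude separated by a
#' controlled delay, embedded in colored noise with generous quiet flanks.
#' The open fraction is fixed at 0.3 (the midpoint of the usual 0.1-0.5
#' range) and the single-channel current is scaled so the expected filtered
#' peak equals `amplitude`; per-event binomial and reclosure stochasticity
#' remain.
#'
#' @param separations Vector of pair separations (s).
#' @param n_trials Trials per separation.
#' @param amplitude Nominal expected peak amplitude (pA, negative).
#' @param open_fraction Fixed open fraction for both events.
#' @param window_s Trial window length (s).
#' @param params,noise,seed As elsewhere.
#' @return A list of trials; each trial is a list with `record`, `truth` and
#'   `separation_s`.
#' @export
generate_pairs_assay <- function(separations = c(1e-4, 2e-4, 2.5e-4, 4e-4, 8e-4, 1.6e-3),
                                 n_trials = 20L, amplitude = -30,
                                 open_fraction = 0.3, window_s = 0.05,
                                 params = ampa_params(),
                                 noise = noise_params(), seed = NULL) {
  if (any(separations <= 0)) stop_config("separations must be positive")
  if (n_trials == 0L) return(list())
  pf <- peak_response_factor(params)
  i_ch <- abs(amplitude) / (params$n_receptors * open_fraction * pf)
  wlen <- round(window_s / params$dt)
  off <- round(0.35 * wlen)
  run <- function() {
    out <- list()
    for (sep in separations) {
      ds <- round(sep / params$dt)
      for (j in seq_len(n_trials)) {
        n0 <- rbinom(2, params$n_receptors, open_fraction)
        tr <- build_trial(c(off, off + ds), n0, wlen, params, noise, i_ch)
        tr$separation_s <- sep
        out[[length(out) + 1L]] <- tr
      }
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Amplitude-sensitivity assay
#'
#' Isolated EPSCs, one per trial window, with the single-channel current
#' scaled so the expected filtered peak equals each target amplitude
#' (sweep default -1 to -30 pA); colored noise added. Events do not overlap
#' in this assay.
#'
#' @param amplitudes Target peak amplitudes (pA, all negative).
#' @param n_trials Trials per amplitude.
#' @inheritParams generate_pairs_assay
#' @return A list of trials; each a list with `record`, `truth` and
#'   `target_pA`.
#' @export
generate_amplitude_assay <- function(amplitudes = c(-1, -2, -5, -8, -11, -14,
                                                    -17, -20, -25, -30),
                                     n_trials = 20L, open_fraction = 0.3,
                                     window_s = 0.035,
                                     params = ampa_params(),
                                     noise = noise_params(), seed = NULL) {
  if (any(amplitudes >= 0)) stop_domain("amplitudes must be negative")
  if (n_trials == 0L) return(list())
  pf <- peak_response_factor(params)
  wlen <- round(window_s / params$dt)
  off <- round(0.4 * wlen)
  run <- function() {
    out <- list()
    for (A in amplitudes) {
      i_ch <- abs(A) / (params$n_receptors * open_fraction * pf)
      n0 <- rbinom(n_trials, params$n_receptors, open_fraction)
      for (j in seq_len(n_trials)) {
        tr <- build_trial(off, n0[j], wlen, params, noise, i_ch)
        tr$target_pA <- A
        out[[length(out) + 1L]] <- tr
      }
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Multiquantal release simulation (staged)
#'
#' Fixes the transmitter content of each fusion event to an integer number of
#' quanta `q >= 1` (shifted Poisson with the stated mean) and produces
#' amplitude samples at three stages between ligand binding and
#' deconvolution:
#' * stage 1: the number of channels opened by each event
#'   (`Binomial(n_receptors, min(q * quantum_fraction, 1))`), in channel
#'   counts;
#' * stage 2: the peak magnitude of each event's filtered stochastic
#'   waveform (reclosure + membrane filtering), in pA;
#' * stage 3: a full Poisson-timed record with colored noise, returned with
#'   ground truth for downstream deconvolution.
#'
#' Preset A of the staging study: 150 receptors, quantum 0.1 of saturation
#' (15 channels), mean 4 quanta, 10 pA RMS noise. Preset B: 300 receptors,
#' quantum 0.125 (37.5 channels).
#'
#' @param stage 1, 2 or 3.
#' @param n_events Number of fusion events.
#' @param n_receptors Receptor pool size.
#' @param quantum_fraction Fraction of the pool one quantum saturates.
#' @param mean_quanta Mean quanta per fusion event.
#' @param rate Event rate for the stage-3 record (events/s).
#' @param params Base `ampa_params` (receptor count is overridden).
#' @param noise A `noise_params` (stage 3 only).
#' @param seed Optional seed.
#' @return Stages 1-2: a list with `amplitudes` (numeric) and `q` (integer
#'   quanta). Stage 3: additionally `record` and `truth` as in
#'   [generate_poisson_record()].
#' @export
generate_multiquantal <- function(stage, n_events = 8000L, n_receptors = 150L,
                                  quantum_fraction = 0.1, mean_quanta = 4,
                                  rate = 50, params = ampa_params(),
                                  noise = noise_params(), seed = NULL) {
  if (!stage %in% 1:3) stop_config("`stage` must be 1, 2 or 3")
  if (mean_quanta < 1) stop_config("`mean_quanta` must be >= 1")
  pars <- params
  pars$n_receptors <- as.integer(n_receptors)
  run <- function() {
    q <- 1L + rpois(n_events, mean_quanta - 1)
    p_open <- pmin(q * quantum_fraction, 1)
    n0 <- rbinom(n_events, n_receptors, p_open)
    if (stage == 1) {
      return(list(amplitudes = as.numeric(n0) * pars$i_channel, q = q))
    }
    if (stage == 2) {
      support <- ceiling(12 * pars$tau_close / pars$dt)
      cnts <- sim_open_counts(n0, support, pars)
      peaks <- apply(cnts, 2, function(cc) {
        max(rc_lowpass(cc * pars$i_channel, pars$dt, pars$tau_membrane))
      })
      return(list(amplitudes = peaks, q = q))
    }
    duration <- n_events / rate
    n <- round(duration / pars$dt)
    idx <- sort(sample.int(n, n_events, replace = TRUE))
    rec <- assemble_record(idx, n0, n, pars, noise)
    pf <- peak_response_factor(pars)
    list(amplitudes = as.numeric(n0) * pars$i_channel * pf, q = q,
         record = rec$record,
         truth = tibble(time_s = (idx - 1) * pars$dt,
                        true_amplitude_pA = -pars$i_channel * n0 * pf,
                        n_open0 = as.integer(n0), q = q))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "stage") <- stage
  out
}
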