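---
title: "Blind deconvolution of EPSC records: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blind deconvolution of EPSC records: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Whole-cell recordings of spontaneous synaptic activity are often *multiphasic*:
excitatory postsynaptic currents (EPSCs) of widely varying amplitude arrive so
densely that their ~1-2 ms waveforms overlap. Event statistics — rates, amplitude
distributions, inter-event intervals — are nonetheless what mechanistic models
of transmitter release are tested against. `epscdeconv` recovers them by *blind
deconvolution*: the recorded current `x` is modelled as

```
x = f * s + n
```

where `s >= 0` is a sparse train of release masses (one spike of mass `A` per
vesicle-fusion event, in pA under the normalization below), `f <= 0` is the
stereotyped unitary EPSC waveform (the impulse response), `*` is causal
convolution, and `n` is additive Gaussian noise. Both `s` and `f` are inferred
from `x` alone.

Two conventions remove the scale and shift degeneracies inherent in the
factorization `f * s`:

* **peak normalization**: `min(f) = -1`, so an isolated event's deconvolved
  mass equals the magnitude of its peak current in pA;
* **onset alignment**: the filter is rotated so that its onset (first tap at
  5% of peak) sits at lag zero, and event times are reported at filter onset.

# The two alternating steps

## Deconvolution: quantified maximum entropy

With `f` held fixed, the signal is the maximizer of a posterior whose log is
(up to constants)

```
-Phi(s) = -chi2(s) / (2 sigma^2) - alpha * H(s; m)
H(s; m) = sum_i [ m - s_i + s_i log(s_i / m) ]
```

`H` is the negentropy of the quantified maximum-entropy (QME) prior relative
to a small default level `m`: convex, differentiable, zero only at `s = m`,
and enforcing positivity because its gradient diverges at zero. `chi2` is the
sum of squared residuals over the *valid region* (the first `L_f - 1` samples
are excluded, so events that started before the record are not penalized).

The minimizer is found by a truncated-Newton method: preconditioned conjugate
gradients on the Hessian `A'A / sigma^2 + alpha diag(1/s)` with feasibility
safeguards, converged to a relative gradient tolerance of `1e-6` in the
entropic metric (`diag(s)`-weighted, the natural metric of this prior).
Convolutions are applied by FFT; records longer than 8192 samples are solved
in overlapping chunks (margin 4 filter lengths, central region kept), which
makes the run time close to linear in the record length.

The two hyperparameters are set by the evidence framework at the classic
self-consistent point

```
2 * alpha * H(s_hat) = G,   sigma^2 = chi2(s_hat) / (N_valid - G),
G = tr[ B (B + alpha I)^-1 ],  B = diag(sqrt(s)) (A'A / sigma^2) diag(sqrt(s))
```

`G` counts the "good" (data-determined) degrees of freedom. Two numerical
choices matter here:

* The self-consistent point is found by **bracketing and bisecting** the
  residual `2 alpha H - G` over `log(alpha)`, with the inner `(s, sigma)`
  solves fully converged (and warm-started) at each trial value. The naive
  fixed-point iteration `alpha <- G / (2H)` contracts at a ratio of ~0.98 per
  step on realistic records — the background part of the signal dominates both
  `H` and `G`, making the fixed point nearly neutral — and needs dozens of
  iterations; the root-find reaches the same point in about ten.
* `G` needs the eigenvalues of `B`. They are computed exactly (dense
  eigendecomposition) up to 1024 samples. Above that, event-dominated samples
  (`s > 10 m`) are collected into dense blocks (split wherever the filter
  autocorrelation has decayed, block size capped), and the smooth background
  contributes through a spectral (Szegő) approximation: each background sample
  `i` adds `mean_w [ l / (l + alpha) ]` with `l = s_i |F(w)|^2 / sigma^2`.
  A seeded Hutchinson trace estimator is retained as an option and
  cross-checked against the dense route in the tests; it is far too slow to
  sit inside the evidence loop.

A switch to a Gaussian prior (`prior_kind = "gaussian"`) turns the same
machinery into a linear Wiener filter (`wiener_deconvolve()`), which on
circularly padded data equals the closed-form spectral solution — a useful
cross-check and a conventional non-sparse fallback.

## Filter estimation: sign-constrained Wiener-Hopf

With the sparse representation fixed, the filter minimizing `||x - s * f||^2`
solves the Wiener-Hopf (Toeplitz normal) equations `C_ss * f = C_xs`, subject
to `f <= 0`. The constrained solve is nonnegative least squares on `-f`
(Lawson-Hanson active set) applied to the Cholesky-transformed system, with a
ridge of `1e-6 C_ss[0]` because a sparse `s` leaves the Toeplitz form nearly
singular between events. The solution is peak-normalized and the scale factor
is carried back to the signal.

The correlations are computed from the **event-delta representation**: each
detected event's mass placed at its centroid (linearly split across the two
neighbouring samples), not from the raw thresholded dense signal. The dense
MAP solution spreads each event's mass over the filter's resolution width
(~5-10 samples at the default kinetics); used directly, that spread acts as an
extra smearing kernel and measurably corrupts the recovered filter (normalized
RMS error 0.6 on exact synthetic data, versus < 1e-12 with event deltas).

## The outer loop

`run_blind()` alternates the two steps — evidence-optimized deconvolution,
event extraction, filter re-estimation, onset alignment — until the filter's
relative L2 change falls below `filter_change_tol`. Filter updates are damped
50/50 against the previous filter: events near the detection threshold enter
and leave the sparse representation between iterations, which leaves a few
percent of irreducible wobble in the re-estimated filter; the default
tolerance of 1e-2 marks genuine shape convergence. On clean synthetic records
the correct filter is reached within one to three iterations from the generic
difference-of-exponentials template (0.25 ms rise, 1 ms decay, 300 taps =
15 ms support at 50 us: the rise plus ~10 decay constants).

Per-event times and amplitudes are deliberately **not** re-optimized after
thresholding: with overlapping events that refinement is known to converge to
wrong configurations. The only amplitude correction applied is global: the
filter-fit scale factor multiplies all event masses, compensating the uniform
part of the entropic prior's shrinkage.

# Event extraction

The dense MAP signal is reduced to events in four steps: samples above a mark
level (`1 sigma_s`) are grouped, bridging gaps of up to 2 samples; merged
groups are split at interior valleys deeper than half the smaller adjacent
peak, provided the peaks are at least 3 samples apart (sub-risetime doublets
are unresolvable in principle); each group's mass is integrated over its span
plus 4 samples of tail on either side; and a group becomes an event when its
mass exceeds `k sigma_s` with `k = 4`. Here `sigma_s = sigma_raw / ||f||_2`
is the noise-equivalent mass — the mass whose fitted response has unit
signal-to-noise against the raw noise SD. The mass (not per-sample) threshold
is essential: the entropic prior *prefers* spreading a given mass (spreading
lowers `H`), so even large events rarely exceed `4 sigma_s` in any single
sample while their group mass is accurate. With the evidence-selected
hyperparameters a 10 s pure-noise record produces no events at all (the prior
saturates and the signal collapses to `m`), comfortably meeting the
calibration target of < 0.1 expected false events.

# Noise model and whitening

Recording noise is rarely white; its correlation time (~1 ms here) is
comparable to the EPSC decay, which is exactly what limits temporal
resolution. The likelihood therefore whitens residuals with the inverse of a
fitted AR(1) spectrum by default (coefficient from the lag-1 autocorrelation
of event-free stretches, or from a user-supplied correlation time). The
practical difference is large: under 1 ms-correlated noise at 10 pA RMS, the
white-noise likelihood cannot separate two EPSCs 250 us apart at all — their
deconvolved mass fuses into a single blob — while the whitened likelihood
resolves them cleanly. Whitening can be disabled
(`noise_model(whitening = FALSE)`) for genuinely white noise.

`sigma` inside the whitened likelihood is the AR(1) innovation scale; the raw
noise SD used for thresholds is estimated robustly (MAD) from the record
itself, and `m` defaults to 1% of it: prior mass well below the noise floor,
encoding sparseness. Initialization of `sigma` uses the MAD of the
first-differenced record, which is insensitive to events.

# The synthetic generator

The simulator reproduces the stochastic structure of AMPA-receptor EPSCs: at
each event a binomial number of a 150-receptor pool opens instantaneously
(open fraction 0.1-0.5, drawn uniformly for Poisson records; fixed at the 0.3
midpoint for the calibrated benchmark assays so that the nominal amplitude is
controlled), each channel recloses independently with an exponential ~1 ms
lifetime, the summed single-channel currents (1 pA each) are low-pass
filtered by the 0.25 ms membrane time constant (first-order update
`y <- y + (dt/tau)(u - y)`), and the trace is sampled at 50 us. Additive
noise is white Gaussian passed through a single-pole low-pass with a 1 ms
correlation time, rescaled to exactly 10 pA RMS. Event times are Poisson;
the complex-record preset draws peak amplitudes from a gamma distribution
(shape 3, mean 40 pA — values chosen to mimic high-rate auditory-synapse
records and produce a realistic mix of isolated and overlapping events)
with exponential inter-event intervals at 100 events/s.

The multiquantal mode fixes each event's transmitter content to an integer
number of quanta `q >= 1`. The paper-level constraint is only the mean (4);
the package draws `q` from a shifted Poisson (`1 + Poisson(mean - 1)`), an
assumption stated prominently here and exposed as configuration. Three stages
are observable: the binomial channel-opening counts, the filtered stochastic
peak amplitudes, and a full noisy record for deconvolution. One consequence
worth knowing: at 150 receptors with a 15-channel quantum, the binomial
opening noise alone (SD 3.7-5.7 channels) spaces adjacent quantal modes only
2.6-4 SDs apart, so the *stage-one* histogram already shows only shallow
modes (valley-to-peak ratio ~0.8) under shifted-Poisson weights; with 300
receptors and a 37.5-channel quantum the modes are 6.5 SDs apart and resolve
sharply (< 0.35). Downstream stages only blur further.

What the generator does **not** emulate: multi-state receptor kinetics
(desensitization), multiple synapses with distinct filters, baseline drift,
and non-stationary noise. Passing benchmarks on these records therefore
demonstrates correct inference under the stated stochastic model, not
robustness to every pathology of real recordings.

# Benchmark scoring choices

A trial of the paired-pulse assay is "classified correctly" iff exactly two
events are detected within +/-1 ms of the true pair and each true event is
matched within `min(250 us, separation/2)`; the amplitude assay analogously
requires exactly one matched detection. The +/-1 ms analysis window is a
package choice: the generation window (tens of ms) exists only to separate
trials, and exact-count scoring over it would mostly measure the false-event
rate in empty stretches. Matching is an exact non-crossing assignment
(maximum cardinality, then minimum total |dt|), which provably dominates
greedy nearest-first matching on crossed configurations. Interval
distributions are fitted by the closed-form exponential MLE.

Under these conditions the detection of small events is bounded by the noise
physics: the whitened matched-filter SNR of a -14 pA EPSC in 1 ms-correlated
10 pA RMS noise is about 2.3, with a corresponding lower bound of ~6 pA on
the SD of any unbiased amplitude estimate. The benchmark numbers the package
reports should be read against that bound; the vignette's companion README
shows the values the acceptance script actually computes.

# Problem sizes and determinism

The shipped tests run the benchmarks at desk scale: 200 trials per headline
condition, 50 trials per amplitude in the sweep, a 500-event complex record,
and a 2000-event multiquantal record — sizes at which the Monte-Carlo error
of an accuracy estimate is ~3 percentage points. All generators and the full
pipeline are bit-reproducible given a seed; the only internal randomness (the
optional Hutchinson trace probes) is seeded explicitly.

# Known limitations

* Amplitudes carry the entropic prior's shrinkage; the global filter-fit
  rescale removes the uniform part but event-to-event variability of the
  shrinkage inflates the amplitude-error SD by roughly half over the matched
  bound at the evidence-selected regularization.
* The AR(1) whitening model is a single-pole approximation; strongly
  structured noise spectra (line pickup, 1/f drift) are out of scope.
* Chunked processing assumes hyperparameters are stationary across the
  record.
* The evidence approximations (Laplace log-determinant, block/spectral
  eigenvalues) are accurate for sparse records; densely overlapping records
  push `G` toward its approximation error.
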