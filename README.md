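# epscdeconv

Blind deconvolution of multiphasic excitatory postsynaptic current (EPSC)
records.

Whole-cell recordings of spontaneous synaptic activity are often so dense
that individual EPSCs overlap into multiphasic waveforms, yet the questions
asked of such data — release rates, amplitude distributions, inter-event
intervals, quantal structure — all require a per-event decomposition.
`epscdeconv` is for electrophysiologists (and anyone with a train of sparse,
stereotyped, negative-going transients in correlated noise) who need that
decomposition without hand-tuning templates or thresholds.

## The model

The recorded current is modelled as a convolution plus noise,

```
x[t] = sum_k f[k] s[t-k] + n[t]
```

with `s >= 0` a sparse train of release masses, `f <= 0` the stereotyped
unitary EPSC (peak-normalized to `min(f) = -1`, so an isolated event's mass
equals its peak current in pA), and `n` additive Gaussian noise with ~1 ms
correlation time. Both `s` and `f` are inferred from `x` alone by
alternating two steps, in the manner of expectation maximization:

1. **Deconvolution.** Maximum a posteriori estimation of `s` under the
   quantified maximum-entropy prior: minimize
   `chi^2/(2 sigma^2) + alpha * H(s; m)` with the negentropy
   `H = sum(m - s + s log(s/m))`, which enforces positivity and sparseness
   while staying convex. The regularization strength `alpha` and noise scale
   `sigma` are selected automatically by the evidence framework
   (`2 alpha H = G` with `G = tr[B(B + alpha I)^{-1}]` the good
   measurements, and `sigma^2 = chi^2 / (N - G)`). Correlated noise is
   whitened by a fitted AR(1) spectrum inside the likelihood.
2. **Filter estimation.** The impulse response solves the Wiener-Hopf
   (Toeplitz) normal equations `C_ss * f = C_xs` under the constraint
   `f <= 0` (nonnegative least squares on `-f`), estimated from the sparse
   event representation obtained by thresholding the deconvolved signal.

A switch to a Gaussian prior turns step 1 into a classical linear Wiener
filter. A stochastic AMPA-receptor simulator (binomial channel opening,
exponential reclosure, membrane filtering, colored noise) provides
ground-truthed records for the bundled benchmark assays.

## Worked example

```r
library(epscdeconv)

# a 2 s synthetic record: ~200 overlapping EPSCs at 100 events/s,
# gamma-distributed amplitudes, colored noise at 10 pA RMS
sim <- generate_complex_record(n_events = 200, rate = 100, seed = 7)
sim$record
#> <ts_record> 40000 samples, dt = 5e-05 s (2 s total), range [-141, 39] pA

fit <- run_blind(sim$record, blind_config(max_outer_iters = 4L))
fit
#> <blind_result> 335 events, 2 outer iteration(s), converged
#>   mean amplitude -33.4 pA, filter 300 taps, alpha = 0.0365, sigma = 2.98

head(generics::tidy(fit), 3)
#> # A tibble: 3 x 4
#>   time_s amplitude_pA mass_pA n_samples
#>    <dbl>        <dbl>   <dbl>     <int>
#> 1 0.0204        -33.4    33.4         8
#> 2 0.0275        -14.9    14.9        10
#> 3 0.0285       -100.     100.        10

# score against the generator's ground truth
m <- match_events(sim$truth, fit$events, window = 2.5e-4)
generics::glance(m)
#> # A tibble: 1 x 4
#>   n_matched n_misses n_false_positives window_s
#> 1       200       32               135  0.00025

filter_recovery_error(fit$filter, true_mean_filter())
#> [1] 0.03705593
```

Reading the output: the blind loop converged in two alternations; the
evidence framework settled at `alpha = 0.037` with an innovation noise scale
of 3.0 pA (the AR(1)-whitened equivalent of the 10 pA raw RMS). Of the 232
true events, 200 are matched within 250 us; the extra detections are
concentrated at small masses near the detection threshold, the price of
resolving genuinely overlapping events in noise whose correlation time
matches the EPSC decay. The re-estimated impulse response is within 3.7%
(normalized RMS) of the generator's true mean kinetics, starting from a
generic difference-of-exponentials template.

Each result type has plotting support: `autoplot(fit, sim$record)` overlays
detected events on the trace, `plot_filter(fit$filter, true_mean_filter())`
compares impulse responses, and `autoplot()` on an accuracy curve from
`pairs_accuracy()` / `amplitude_accuracy()` draws the benchmark curves with
Wilson confidence bands.

## Command line

A thin wrapper over the same functions lives at `inst/cli/epscdeconv.R`:

```sh
Rscript inst/cli/epscdeconv.R simulate --preset complex --events 200 --seed 7 --out sim/
Rscript inst/cli/epscdeconv.R deconvolve --input sim/record.txt --out out/
Rscript inst/cli/epscdeconv.R deconvolve --input sim/record.txt --prior gaussian --alpha 0.5 --sigma 10 --out wiener/
```

`deconvolve` writes `events.csv`, `filter.csv`, the dense signal and a
diagnostics JSON; `--alpha/--sigma` override the automatic evidence
estimation, `--filter` supplies a known impulse response, and
`--prior gaussian` switches to the Wiener mode.

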