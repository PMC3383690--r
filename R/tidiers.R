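#' Tidy the events of a blind deconvolution result
#'
#' @param x A `blind_result`.
#' @param ... Unused.
#' @return The event table as a tibble (one row per detected event).
#' @export
tidy.blind_result <- function(x, ...) {
  as_tibble(x$events)
}

#' One-row summary of a blind deconvolution result
#'
#' @param x A `blind_result`.
#' @param ... Unused.
#' @return A one-row tibble: event count, mean amplitude, selected alpha and
#'   sigma, filter-fit scale, outer iterations, convergence flag.
#' @export
glance.blind_result <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    mean_amplitude_pA = if (nrow(x$events)) mean(x$events$amplitude_pA) else NA_real_,
    alpha = x$hyper$alpha,
    sigma = x$hyper$sigma %||% NA_real_,
    sigma_raw = x$sigma_raw,
    scale = x$scale,
    n_outer = x$n_outer,
    converged = x$converged)
}

#' @export
tidy.match_result <- function(x, ...) {
  as_tibble(x$pairs)
}

#' @export
glance.match_result <- function(x, ...) {
  tibble(n_matched = nrow(x$pairs), n_misses = length(x$misses),
         n_false_positives = length(x$false_positives), window_s = x$window)
}

#' @export
tidy.posterior_diagnostics <- function(x, ...) {
  tibble(H = x$H, chi2 = x$chi2, G = x$G, log_evidence = x$log_evidence,
         alpha = x$alpha, sigma = x$sigma, n_iterations = x$n_iterations)
}
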