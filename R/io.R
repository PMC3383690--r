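#' Read a current-trace record from disk
#'
#' Supported formats:
#' * `csv2col`: CSV with header and columns `(time_s, current_pA)`; the time
#'   base must be uniform to 1e-6 relative tolerance.
#' * `txt1col`: one current value per line, with a `# dt=<seconds>` header
#'   line.
#' * `raw_f32`: little-endian 32-bit floats; `dt_override` is required.
#'
#' @param path File path.
#' @param format One of `"csv2col"`, `"txt1col"`, `"raw_f32"`.
#' @param dt_override Sampling interval (s) overriding/replacing the one in
#'   the file.
#' @return A `ts_record`.
#' @export
read_record <- function(path, format = c("csv2col", "txt1col", "raw_f32"),
                        dt_override = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  if (format == "csv2col") {
    df <- read.csv(path)
    if (ncol(df) < 2L) stop_data("csv2col requires two columns (time_s, current_pA)")
    tt <- df[[1]]
    dts <- diff(tt)
    if (length(dts)) {
      dt <- median(dts)
      if (any(abs(dts - dt) > 1e-6 * max(abs(dt), 1e-12))) {
        stop_data("non-uniform time base in csv2col record")
      }
    } else {
      dt <- dt_override %||% stop_config("single-sample csv needs `dt_override`")
    }
    return(ts_record(df[[2]], dt = dt_override %||% dt, t0 = tt[1]))
  }
  if (format == "txt1col") {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    dt <- dt_override
    dtl <- grep("^#\\s*dt=", hdr, value = TRUE)
    if (is.null(dt)) {
      if (!length(dtl)) stop_config("txt1col record lacks a '# dt=<seconds>' header")
      dt <- as.numeric(sub("^#\\s*dt=", "", dtl[1]))
      if (!is.finite(dt)) stop_config("unparseable dt header in txt1col record")
    }
    vals <- as.numeric(lines[!grepl("^#", lines) & nzchar(lines)])
    return(ts_record(vals, dt = dt))
  }
  # raw_f32
  if (is.null(dt_override)) {
    stop_config("raw_f32 requires `dt_override` (no embedded time base)")
  }
  n <- file.info(path)$size / 4
  vals <- readBin(path, "numeric", n = n, size = 4, endian = "little")
  ts_record(vals, dt = dt_override)
}

#' Write a record as one-value-per-line text
#'
#' @param record A `ts_record`.
#' @param path Output path.
#' @export
write_record_txt <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g", record$dt), con)
  writeLines(sprintf("%.10g", record$samples), con)
  invisible(path)
}

#' Read/write an impulse-response filter as CSV
#'
#' Two columns `(tap_index, value)` with a header row, written at 17
#' significant digits so round trips are bit-stable.
#'
#' @param filter An `impulse_response`.
#' @param path File path.
#' @param dt Sampling interval assigned on read (s).
#' @return `write_filter_csv` returns the path; `read_filter_csv` an
#'   `impulse_response`.
#' @export
write_filter_csv <- function(filter, path) {
  df <- data.frame(tap_index = seq_along(filter$taps) - 1L,
                   value = sprintf("%.17g", filter$taps))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_filter_csv
#' @export
read_filter_csv <- function(path, dt = 5e-5) {
  df <- read.csv(path)
  impulse_response(as.numeric(df$value), dt = dt, normalize = TRUE)
}

#' Write an event table as CSV
#'
#' Columns `(event_index, time_s, amplitude_pA, mass_pA, n_samples)`,
#' deterministic ordering by time.
#'
#' @param events An `event_table`.
#' @param path Output path.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(
    event_index = seq_len(nrow(events)),
    time_s = sprintf("%.10g", events$time_s),
    amplitude_pA = sprintf("%.10g", events$amplitude_pA),
    mass_pA = sprintf("%.10g", events$mass_pA),
    n_samples = events$n_samples)
  if (!nrow(events)) {
    df <- df[0, , drop = FALSE]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#' @param path File path.
#' @return An `event_table`.
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path)
  event_table(time_s = df$time_s, amplitude_pA = df$amplitude_pA,
              mass_pA = df$mass_pA, n_samples = df$n_samples)
}

#' Write the full output set of a blind run
#'
#' Writes `events.csv`, `filter.csv`, `signal.txt` (dense deconvolved signal,
#' one value per line) and `diagnostics.json` (per-outer-iteration alpha,
#' sigma, H, chi2, G, event count) into a directory. All outputs are
#' deterministic given the result.
#'
#' @param result A `blind_result`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_outputs <- function(result, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) stop_config(sprintf("cannot create output directory: %s", outdir))
  paths <- c(
    events = file.path(outdir, "events.csv"),
    filter = file.path(outdir, "filter.csv"),
    signal = file.path(outdir, "signal.txt"),
    diagnostics = file.path(outdir, "diagnostics.json"))
  write_events_csv(result$events, paths["events"])
  write_filter_csv(result$filter, paths["filter"])
  write_record_txt(ts_record(result$signal$values, dt = result$signal$dt),
                   paths["signal"])
  di <- result$diagnostics
  jsonlite::write_json(
    list(converged = result$converged, n_outer = result$n_outer,
         scale = result$scale,
         iterations = di),
    paths["diagnostics"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

# Run configuration ------------------------------------------------------

#' Assemble, serialize and parse a run configuration
#'
#' A `run_config` collects every tunable of a reproducible run (generator,
#' noise, deconvolution, blind-loop and assay settings plus seed and paths).
#' It round-trips losslessly through JSON; unknown keys are rejected on
#' parse.
#'
#' @param ampa An `ampa_params`.
#' @param noise_sim A `noise_params` (synthetic noise).
#' @param hyper A `qme_hyperparameters`.
#' @param blind A `blind_config`.
#' @param noise_fit A `noise_model` (likelihood noise treatment).
#' @param seed Integer seed.
#' @param paths Named list of file paths.
#' @param log_level One of `"debug"`, `"info"`, `"warning"`, `"error"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(ampa = ampa_params(), noise_sim = noise_params(),
                       hyper = qme_hyperparameters(), blind = blind_config(),
                       noise_fit = noise_model(), seed = 1L,
                       paths = list(), log_level = "info") {
  if (!log_level %in% c("debug", "info", "warning", "error")) {
    stop_config("invalid log level")
  }
  structure(
    list(ampa = ampa, noise_sim = noise_sim, hyper = hyper, blind = blind,
         noise_fit = noise_fit, seed = as.integer(seed), paths = paths,
         log_level = log_level),
    class = "run_config")
}

config_field_names <- list(
  ampa = c("n_receptors", "i_channel", "tau_close", "tau_membrane", "dt"),
  noise_sim = c("rms", "correlation_time", "seed"),
  hyper = c("alpha", "sigma", "m", "max_newton_iters", "grad_tol",
            "alpha_fixed", "sigma_fixed", "prior_kind"),
  blind = c("max_outer_iters", "filter_change_tol", "threshold_multiplier",
            "mark_multiplier", "grouping_gap", "split_ratio", "mass_pad",
            "initial_filter", "filter_damping", "seed"),
  noise_fit = c("sigma", "correlation_time", "whitening"))

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_config_json <- function(config, path) {
  ser <- lapply(unclass(config), function(part) {
    if (is.list(part) && !is.null(attr(part, "class"))) unclass(part) else part
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known_top <- c("ampa", "noise_sim", "hyper", "blind", "noise_fit", "seed",
                 "paths", "log_level")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) {
    stop_config(sprintf("unknown configuration keys: %s",
                        paste(extra, collapse = ", ")))
  }
  for (part in names(config_field_names)) {
    extra <- setdiff(names(raw[[part]]), config_field_names[[part]])
    if (length(extra)) {
      stop_config(sprintf("unknown keys in `%s`: %s", part,
                          paste(extra, collapse = ", ")))
    }
  }
  nn <- function(x) if (is.null(x) || (is.list(x) && !length(x))) NULL else x
  a <- raw$ampa
  h <- raw$hyper
  b <- raw$blind
  nf <- raw$noise_fit
  ns <- raw$noise_sim
  run_config(
    ampa = ampa_params(a$n_receptors, a$i_channel, a$tau_close,
                       a$tau_membrane, a$dt),
    noise_sim = noise_params(ns$rms, ns$correlation_time, nn(ns$seed)),
    hyper = qme_hyperparameters(h$alpha, nn(h$sigma), nn(h$m),
                                h$max_newton_iters, h$grad_tol,
                                h$alpha_fixed, h$sigma_fixed, h$prior_kind),
    blind = blind_config(b$max_outer_iters, b$filter_change_tol,
                         b$threshold_multiplier, b$mark_multiplier,
                         b$grouping_gap, b$split_ratio, b$mass_pad,
                         b$initial_filter, b$filter_damping, nn(b$seed)),
    noise_fit = noise_model(nn(nf$sigma), nn(nf$correlation_time),
                            nf$whitening),
    seed = raw$seed,
    paths = as.list(raw$paths),
    log_level = raw$log_level)
}
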