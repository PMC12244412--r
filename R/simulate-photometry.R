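#' Configuration for the synthetic photometry generator
#'
#' The emitted trace mimics a dLight photometry channel whose excitation
#' light is amplitude-modulated at 167 Hz and sampled at 2,000 Hz: the
#' carrier's envelope is a constant baseline plus Gaussian-shaped
#' transients -- a positive peak 0.83 s after each successful reach and a
#' negative dip 1.6 s after each failed reach -- plus white noise on the
#' samples. `snr` is the transient amplitude over the noise SD.
#'
#' @param sample_rate_hz sampling rate (default 2000).
#' @param carrier_hz modulation frequency (default 167).
#' @param baseline_amp carrier envelope baseline (arbitrary units).
#' @param transient_amp success-transient amplitude (failures use the
#'   negated amplitude).
#' @param noise_sd white-noise SD; defaults to `transient_amp / snr`.
#' @param snr transient-amplitude-to-noise ratio used when `noise_sd` is
#'   not given (default 2).
#' @param success_latency_s envelope peak after a success (default 0.83).
#' @param failure_latency_s envelope dip after a failure (default 1.6).
#' @param transient_width_s Gaussian SD of the transients, seconds.
#' @return list of class `"photometry_gen_config"`.
#' @export
photometry_gen_config <- function(sample_rate_hz = 2000, carrier_hz = 167,
                                  baseline_amp = 1, transient_amp = 0.5,
                                  noise_sd = NULL, snr = 2,
                                  success_latency_s = 0.83,
                                  failure_latency_s = 1.6,
                                  transient_width_s = 0.2) {
  if (is.null(noise_sd)) noise_sd <- transient_amp / snr
  stopifnot(sample_rate_hz > 2 * carrier_hz, baseline_amp > 0,
            noise_sd >= 0, transient_width_s > 0)
  structure(list(sample_rate_hz = sample_rate_hz, carrier_hz = carrier_hz,
                 baseline_amp = baseline_amp, transient_amp = transient_amp,
                 noise_sd = noise_sd,
                 success_latency_s = success_latency_s,
                 failure_latency_s = failure_latency_s,
                 transient_width_s = transient_width_s),
            class = "photometry_gen_config")
}

#' Generate a synthetic photometry trace
#'
#' @param events either a [reach_session()] (success/failure reach times
#'   are extracted) or a list with numeric `success_times` and
#'   `failure_times` (seconds).
#' @param duration_s trace duration; defaults to cover the last event
#'   plus 5 s.
#' @param cfg a [photometry_gen_config()].
#' @param seed integer seed.
#' @return list with `trace` (class `"photometry_trace"`: `samples`,
#'   `sample_rate_hz`, `carrier_hz`) and `truth` (event times,
#'   amplitudes, latencies).
#' @export
generate_photometry <- function(events, duration_s = NULL,
                                cfg = photometry_gen_config(), seed = 1L) {
  stopifnot(inherits(cfg, "photometry_gen_config"))
  if (inherits(events, "reach_session")) {
    rows <- do.call(rbind, lapply(events$trials, function(tr) tr$reaches))
    succ <- rows$t_arm[rows$outcome == "success"]
    fail <- rows$t_arm[is_failure(rows$outcome)]
  } else {
    succ <- events$success_times
    fail <- events$failure_times
  }
  if (is.null(duration_s)) {
    duration_s <- max(c(succ, fail, 10)) + 5
  }
  set.seed(seed)
  fs <- cfg$sample_rate_hz
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  env <- rep(cfg$baseline_amp, length(t))
  add_transients <- function(env, times, latency, amp) {
    for (ev in times) {
      c0 <- ev + latency
      lo <- max(1L, floor((c0 - 4 * cfg$transient_width_s) * fs))
      hi <- min(length(t), ceiling((c0 + 4 * cfg$transient_width_s) * fs))
      if (lo <= hi) {
        idx <- lo:hi
        env[idx] <- env[idx] +
          amp * exp(-0.5 * ((t[idx] - c0) / cfg$transient_width_s)^2)
      }
    }
    env
  }
  env <- add_transients(env, succ, cfg$success_latency_s, cfg$transient_amp)
  env <- add_transients(env, fail, cfg$failure_latency_s, -cfg$transient_amp)
  samples <- env * sin(2 * pi * cfg$carrier_hz * t) +
    stats::rnorm(length(t), 0, cfg$noise_sd)
  trace <- structure(list(samples = samples, sample_rate_hz = fs,
                          carrier_hz = cfg$carrier_hz),
                     class = "photometry_trace")
  list(trace = trace,
       truth = list(config = cfg, seed = seed,
                    success_times = succ, failure_times = fail))
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> %.1f s at %g Hz (carrier %g Hz)\n",
              length(x$samples) / x$sample_rate_hz, x$sample_rate_hz,
              x$carrier_hz))
  invisible(x)
}
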