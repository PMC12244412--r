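#' Demodulation configuration
#'
#' Parameters of the band-pass + multitaper power pipeline: a moving
#' window of 0.1 s stepped every 0.01 s, time-bandwidth product 3 with 2
#' tapers, a 120--200 Hz analysis band around the 167-Hz carrier, a 30-s
#' trailing baseline for the z-score, and a 5-sample median filter.
#'
#' @param window_s spectrogram window, seconds.
#' @param step_s spectrogram step, seconds.
#' @param time_bandwidth multitaper time-bandwidth product NW.
#' @param n_tapers number of Slepian tapers.
#' @param band analysis band `[lo, hi]`, Hz.
#' @param baseline_s rolling-baseline duration for the z-score, seconds.
#' @param median_width median-filter width, output samples (odd; 1 is a
#'   no-op).
#' @param filter_order order of the Butterworth band-pass.
#' @return list of class `"demod_config"`.
#' @export
demod_config <- function(window_s = 0.1, step_s = 0.01, time_bandwidth = 3,
                         n_tapers = 2, band = c(120, 200), baseline_s = 30,
                         median_width = 5, filter_order = 4) {
  stopifnot(step_s <= window_s, n_tapers >= 1, band[1] < band[2],
            median_width >= 1, median_width %% 2 == 1)
  structure(as.list(environment()), class = "demod_config")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as eigenvectors of the standard symmetric tridiagonal matrix
#' whose top eigenvectors are the DPSS sequences; tapers are normalized
#' to unit energy with a positive-mean sign convention.
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return matrix n x k, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 2) {
  stopifnot(n >= 2, k >= 1, k < n)
  w <- nw / n
  tvec <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * tvec) / 2)^2 * cos(2 * pi * w)
  diag_off <- tvec[-1] * (n - tvec[-1]) / 2
  M <- diag(diag_main)
  for (i in seq_len(n - 1)) {
    M[i, i + 1] <- diag_off[i]
    M[i + 1, i] <- diag_off[i]
  }
  eg <- eigen(M, symmetric = TRUE)
  tap <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Demodulate an amplitude-modulated photometry trace
#'
#' Band-passes the raw trace around the carrier, computes a multitaper
#' power spectrogram with the configured window/step/tapers, and returns
#' the mean power over the analysis band as a time series at the step
#' rate (100 Hz by default). Power tracks the squared carrier envelope.
#'
#' @param trace a `"photometry_trace"` (or numeric vector with
#'   `sample_rate_hz` supplied).
#' @param cfg a [demod_config()].
#' @param sample_rate_hz required when `trace` is a bare vector.
#' @return list of class `"photometry_power"`: `time_s` (window
#'   centers), `power`, `step_s`.
#' @export
demodulate <- function(trace, cfg = demod_config(), sample_rate_hz = NULL) {
  if (inherits(trace, "photometry_trace")) {
    x <- trace$samples
    fs <- trace$sample_rate_hz
  } else {
    x <- as.numeric(trace)
    fs <- sample_rate_hz
    if (is.null(fs)) stop("sample_rate_hz required for a bare vector")
  }
  nwin <- round(cfg$window_s * fs)
  nstep <- round(cfg$step_s * fs)
  if (length(x) < nwin) stop("trace shorter than the analysis window")

  bf <- signal::butter(cfg$filter_order, cfg$band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)

  starts <- seq(1L, length(xf) - nwin + 1L, by = nstep)
  frames <- vapply(starts, function(s) xf[s:(s + nwin - 1L)],
                   numeric(nwin))                      # nwin x nframes
  tap <- dpss_tapers(nwin, cfg$time_bandwidth, cfg$n_tapers)
  freqs <- (seq_len(nwin) - 1) * fs / nwin
  in_band <- freqs >= cfg$band[1] & freqs <= cfg$band[2]
  if (!any(in_band)) stop("no FFT bins inside the analysis band")
  pow <- 0
  for (j in seq_len(cfg$n_tapers)) {
    sp <- stats::mvfft(frames * tap[, j])
    pow <- pow + colMeans(abs(sp[in_band, , drop = FALSE])^2)
  }
  pow <- pow / cfg$n_tapers
  structure(list(time_s = (starts - 1L + nwin / 2) / fs, power = pow,
                 step_s = cfg$step_s),
            class = "photometry_power")
}

#' Rolling z-score with median filtering
#'
#' Standardizes the power series against a trailing baseline window
#' (mean and SD over the preceding `baseline_s` seconds; the early part
#' of the series uses the expanding window available so far) and then
#' applies a running median of `median_width` samples. Samples whose
#' rolling SD is zero are set to 0 with a warning.
#'
#' @param power a [demodulate()] result (or numeric vector with
#'   `step_s`).
#' @param cfg a [demod_config()] (supplies `baseline_s` and
#'   `median_width`).
#' @param step_s sample step when `power` is a bare vector.
#' @return list of class `"photometry_z"`: `time_s`, `z`, `step_s`.
#' @export
rolling_zscore <- function(power, cfg = demod_config(), step_s = NULL) {
  if (inherits(power, "photometry_power")) {
    x <- power$power
    tt <- power$time_s
    step_s <- power$step_s
  } else {
    x <- as.numeric(power)
    if (is.null(step_s)) stop("step_s required for a bare vector")
    tt <- (seq_along(x) - 1) * step_s
  }
  w <- max(2L, round(cfg$baseline_s / step_s))
  if (length(x) <= w) stop("series shorter than the baseline window")
  csum <- cumsum(x)
  csq <- cumsum(x^2)
  n <- seq_along(x)
  lo <- pmax(0L, n - w)          # trailing window (lo, n]
  cnt <- n - lo
  s1 <- csum - c(0, csum)[lo + 1L]
  s2 <- csq - c(0, csq)[lo + 1L]
  mu <- s1 / cnt
  va <- pmax(0, s2 / cnt - mu^2)
  sdv <- sqrt(va * cnt / pmax(1, cnt - 1))
  z <- numeric(length(x))
  zero_sd <- sdv == 0 | cnt < 2          # burn-in sample has no SD yet
  if (any(zero_sd & cnt >= 2)) {
    warning("zero rolling SD at ", sum(zero_sd & cnt >= 2),
            " samples; z set to 0 there")
  }
  z[!zero_sd] <- (x[!zero_sd] - mu[!zero_sd]) / sdv[!zero_sd]
  if (cfg$median_width > 1) z <- stats::runmed(z, cfg$median_width)
  structure(list(time_s = tt, z = as.numeric(z), step_s = step_s),
            class = "photometry_z")
}

#' Event-aligned average z-score traces
#'
#' Extracts z-score segments around each event, subtracts a pre-event
#' baseline (the mean over `[-0.5, 0)` s for cue-aligned events and over
#' `[-2, -1.5)` s for reach-aligned events, matching the convention of
#' baselining 0.5 s before the cue or 2 s before the arm), and averages
#' per class. Events whose segment exceeds the trace are dropped and
#' counted.
#'
#' @param z a [rolling_zscore()] result.
#' @param events data.frame with columns `t_event` (seconds), `class`
#'   (grouping label) and optionally `align` (`"arm"` default, or
#'   `"cue"`).
#' @param window segment `[a, b]` around the event, seconds.
#' @return list of class `"aligned_transients"`: `rel_time_s`, `classes`
#'   (per class: `mean`, `se`, `n`), `n_dropped`.
#' @export
align_transients <- function(z, events, window = c(-2, 5)) {
  stopifnot(inherits(z, "photometry_z"),
            all(c("t_event", "class") %in% names(events)))
  if (!"align" %in% names(events)) events$align <- "arm"
  step <- z$step_s
  rel <- seq(window[1], window[2], by = step)
  n_dropped <- 0L
  segs <- list()
  for (i in seq_len(nrow(events))) {
    idx0 <- round((events$t_event[i] - z$time_s[1]) / step) + 1L
    idx <- idx0 + round(rel / step)
    if (idx[1] < 1L || idx[length(idx)] > length(z$z)) {
      n_dropped <- n_dropped + 1L
      next
    }
    seg <- z$z[idx]
    bw <- if (events$align[i] == "cue") c(-0.5, 0) else c(-2, -1.5)
    bsel <- rel >= bw[1] & rel < bw[2]
    if (any(bsel)) seg <- seg - mean(seg[bsel])
    cls <- events$class[i]
    segs[[cls]] <- c(segs[[cls]], list(seg))
  }
  classes <- lapply(segs, function(ss) {
    M <- do.call(rbind, ss)
    list(mean = colMeans(M),
         se = apply(M, 2, stats::sd) / sqrt(nrow(M)),
         n = nrow(M))
  })
  structure(list(rel_time_s = rel, classes = classes,
                 n_dropped = n_dropped),
            class = "aligned_transients")
}
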