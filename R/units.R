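#' Construct a unit recording
#'
#' @param unit_id identifier.
#' @param spike_times numeric vector of spike times, seconds; sorted on
#'   construction.
#' @param width_hm spike waveform width at half-maximum, ms.
#' @param duration_s recording duration used for the mean rate; defaults
#'   to the last spike time.
#' @param mean_rate mean firing rate, Hz; computed from the spikes and
#'   duration when not supplied.
#' @return object of class `"unit_recording"` with the unit class filled
#'   in by [classify_unit()].
#' @export
unit_recording <- function(unit_id, spike_times, width_hm,
                           duration_s = NULL, mean_rate = NULL) {
  spike_times <- sort(as.numeric(spike_times))
  if (is.null(duration_s)) {
    duration_s <- if (length(spike_times)) max(spike_times) else 0
  }
  if (is.null(mean_rate)) {
    mean_rate <- if (duration_s > 0) length(spike_times) / duration_s else 0
  }
  structure(list(unit_id = unit_id, spike_times = spike_times,
                 width_hm = width_hm, mean_rate = mean_rate,
                 duration_s = duration_s,
                 unit_class = classify_unit(width_hm, mean_rate)),
            class = "unit_recording")
}

#' @export
print.unit_recording <- function(x, ...) {
  cat(sprintf("<unit_recording> %s: %d spikes, width %.2f ms, %.2f Hz [%s]\n",
              x$unit_id, length(x$spike_times), x$width_hm, x$mean_rate,
              x$unit_class))
  invisible(x)
}

#' Classify a unit from waveform width and mean rate
#'
#' Putative cell types in striatal recordings, keyed on the waveform width
#' at half-maximum and the session-wide mean firing rate:
#'
#' * SPN (striatal projection neuron): width >= 0.22 ms and rate < 4 Hz
#' * TAN (tonically active neuron): width >= 0.22 ms and rate >= 4 Hz
#' * FS (fast spiking): width < 0.22 ms and rate >= 1.25 Hz
#' * low_firing_thin: width < 0.22 ms and rate < 1.25 Hz
#'
#' @param width_hm waveform width at half-maximum, ms (vectorized).
#' @param mean_rate mean firing rate, Hz (vectorized).
#' @return character vector of classes.
#' @export
classify_unit <- function(width_hm, mean_rate) {
  if (any(is.na(width_hm)) || any(is.na(mean_rate))) {
    stop("width and rate must be non-missing")
  }
  stopifnot(all(width_hm >= 0), all(mean_rate >= 0))
  ifelse(width_hm >= 0.22,
         ifelse(mean_rate < 4, "SPN", "TAN"),
         ifelse(mean_rate >= 1.25, "FS", "low_firing_thin"))
}

#' Peri-stimulus time histogram
#'
#' Event-aligned firing rates: for each bin, the mean over events of
#' (spike count in bin) / binwidth. The output conserves spikes: the sum
#' of bin rates times binwidth times the number of events equals the
#' total in-window spike count.
#'
#' @param unit a [unit_recording()] or numeric vector of spike times.
#' @param event_times numeric vector of alignment times, seconds.
#' @param window numeric length-2 `[-a, b]` around each event, seconds.
#' @param binwidth bin width, seconds.
#' @return list of class `"psth"` with `bin_centers`, `rate_hz`,
#'   `n_events`, `binwidth`.
#' @export
psth <- function(unit, event_times, window = c(-2, 5), binwidth = 0.1) {
  spikes <- if (inherits(unit, "unit_recording")) unit$spike_times else unit
  if (!length(event_times)) stop("no events supplied")
  stopifnot(binwidth > 0, length(window) == 2L, window[1] < window[2])
  edges <- seq(window[1], window[2], by = binwidth)
  if (max(edges) < window[2] - 1e-9) edges <- c(edges, max(edges) + binwidth)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (ev in event_times) {
    rel <- spikes - ev
    rel <- rel[rel >= edges[1] & rel < edges[nb + 1L]]
    if (length(rel)) {
      idx <- pmin(nb, 1L + floor((rel - edges[1]) / binwidth))
      counts <- counts + tabulate(idx, nbins = nb)
    }
  }
  structure(list(bin_centers = edges[-(nb + 1L)] + binwidth / 2,
                 rate_hz = counts / (length(event_times) * binwidth),
                 n_events = length(event_times), binwidth = binwidth),
            class = "psth")
}

#' Trial type of a reach for physiology analyses
#'
#' Cued reaches occur within 3 s of cue onset; uncued reaches occur 5 s to
#' 16 s after the cue (capturing pre-cue reaches of the next trial);
#' reaches between 3 s and 5 s are ambiguous (possibly cued at a long
#' delay) and are excluded from analysis. Reaches outside all windows are
#' `"unlabeled"`.
#'
#' @param t_arm reach times, seconds (vectorized).
#' @param t_cue cue onset of the relevant trial, seconds.
#' @return character vector: `"cued"`, `"ambiguous"`, `"uncued"`,
#'   `"unlabeled"`.
#' @export
physiology_trial_type <- function(t_arm, t_cue) {
  stopifnot(!is.na(t_cue))
  rel <- t_arm - t_cue
  ifelse(rel >= 0 & rel < 3, "cued",
         ifelse(rel >= 3 & rel < 5, "ambiguous",
                ifelse(rel >= 5 & rel <= 16, "uncued", "unlabeled")))
}

#' Stratified 50/50 train/test split of trials
#'
#' Randomly assigns half of the trials of each behavioral condition to the
#' training set (floor(n/2) when n is odd) and the remainder to the test
#' set. The same assignment is used for every unit recorded in the same
#' session, so call this once per session. Conditions with fewer than two
#' trials are dropped with a warning.
#'
#' @param trial_ids_by_condition named list: condition -> vector of trial
#'   ids.
#' @param seed integer seed.
#' @return object of class `"split_spec"`: named list per condition with
#'   `train` and `test` id vectors, plus attribute `seed`.
#' @export
train_test_split <- function(trial_ids_by_condition, seed = 1L) {
  stopifnot(is.list(trial_ids_by_condition),
            !is.null(names(trial_ids_by_condition)))
  set.seed(seed)
  out <- list()
  for (cond in names(trial_ids_by_condition)) {
    ids <- trial_ids_by_condition[[cond]]
    if (length(ids) < 2L) {
      warning(sprintf("condition '%s' has fewer than 2 trials; excluded", cond))
      next
    }
    k <- floor(length(ids) / 2)
    train <- sort(sample(ids, k))
    out[[cond]] <- list(train = train, test = sort(setdiff(ids, train)))
  }
  structure(out, class = "split_spec", seed = seed)
}
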