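#' Reach outcome levels
#'
#' Every reach is labelled with one of four outcomes. A reach is a failure
#' unless the mouse successfully grabbed and consumed the pellet; drops,
#' reaches that missed the pellet, and reaches when the pellet was absent
#' all count as failures.
#' @export
reach_outcomes <- c("success", "drop", "missed_pellet", "pellet_missing")

#' Is a reach outcome a failure?
#'
#' @param outcome character vector of outcomes (see [reach_outcomes]).
#' @return logical vector; `TRUE` for every outcome other than `"success"`.
#' @export
is_failure <- function(outcome) {
  stopifnot(all(outcome %in% reach_outcomes))
  outcome != "success"
}

#' Construct a reach table
#'
#' @param t_arm numeric vector, seconds from session start at which the arm
#'   was outstretched.
#' @param outcome character vector of outcomes, recycled if length 1.
#' @return a `data.frame` with columns `t_arm`, `outcome`, sorted by time.
#' @export
reaches <- function(t_arm = numeric(), outcome = character()) {
  if (length(outcome) == 1L && length(t_arm) > 1L) {
    outcome <- rep(outcome, length(t_arm))
  }
  stopifnot(length(t_arm) == length(outcome))
  if (length(t_arm)) {
    stopifnot(all(is.finite(t_arm)), all(t_arm >= 0),
              all(outcome %in% reach_outcomes))
    if (anyDuplicated(t_arm)) {
      stop("overlapping reach times: reach times must be distinct")
    }
  }
  ord <- order(t_arm)
  data.frame(t_arm = as.numeric(t_arm[ord]), outcome = outcome[ord],
             stringsAsFactors = FALSE)
}

#' Construct a single trial
#'
#' A trial spans `[trial_start, trial_end)` in session time. On cue trials
#' the cue turns on at `t_cue`; on cue-omission trials `t_cue` is `NA`.
#' `pellet_presented` records whether a pellet was available after the cue,
#' and `catch` flags the deliberate pellet omissions on cue trials.
#'
#' @param trial_start,trial_end trial bounds, seconds from session start.
#' @param t_cue cue onset (seconds) or `NA` on cue-omission trials.
#' @param cue_present logical.
#' @param pellet_presented logical; pellet available after the cue.
#' @param catch logical; cue presented but pellet deliberately omitted.
#' @param chewing_at_start logical; mouse chewing at trial start.
#' @param inhibition_window optional numeric length-2 `[start, end]`
#'   (seconds, session time) of optogenetic inhibition, or `NULL`.
#' @param distractor_times numeric vector of distractor-flash onsets.
#' @param reaches a reach table from [reaches()].
#' @param trial_id integer id (0-based in serialized files).
#' @return an object of class `"reach_trial"` (a list).
#' @export
trial <- function(trial_start, trial_end, t_cue = NA_real_,
                  cue_present = !is.na(t_cue), pellet_presented = TRUE,
                  catch = cue_present && !pellet_presented,
                  chewing_at_start = FALSE, inhibition_window = NULL,
                  distractor_times = numeric(), reaches = cuedreach::reaches(),
                  trial_id = NA_integer_) {
  stopifnot(is.numeric(trial_start), is.numeric(trial_end),
            trial_start < trial_end)
  if (cue_present) {
    stopifnot(!is.na(t_cue), trial_start <= t_cue, t_cue < trial_end)
  } else {
    t_cue <- NA_real_
  }
  if (!is.null(inhibition_window)) {
    stopifnot(length(inhibition_window) == 2L,
              inhibition_window[1] <= inhibition_window[2],
              inhibition_window[1] >= trial_start,
              inhibition_window[2] <= trial_end)
  }
  structure(list(
    trial_id = as.integer(trial_id),
    trial_start = as.numeric(trial_start),
    trial_end = as.numeric(trial_end),
    t_cue = as.numeric(t_cue),
    cue_present = isTRUE(cue_present),
    pellet_presented = isTRUE(pellet_presented),
    catch = isTRUE(catch),
    chewing_at_start = isTRUE(chewing_at_start),
    inhibition_window = inhibition_window,
    distractor_times = as.numeric(distractor_times),
    reaches = reaches
  ), class = "reach_trial")
}

#' Construct a behavioral session
#'
#' @param trials list of [trial()] objects, ordered in time.
#' @param mouse_id optional identifier.
#' @param session_id optional identifier.
#' @return an object of class `"reach_session"`.
#' @export
reach_session <- function(trials, mouse_id = NA_character_,
                          session_id = NA_character_) {
  stopifnot(is.list(trials), all(vapply(trials, inherits, TRUE, "reach_trial")))
  starts <- vapply(trials, `[[`, 0, "trial_start")
  if (is.unsorted(starts)) stop("trials must be ordered in time")
  for (i in seq_along(trials)) {
    if (is.na(trials[[i]]$trial_id)) trials[[i]]$trial_id <- i - 1L
  }
  structure(list(trials = trials, mouse_id = mouse_id,
                 session_id = session_id), class = "reach_session")
}

#' @export
print.reach_session <- function(x, ...) {
  n <- length(x$trials)
  nr <- sum(vapply(x$trials, function(tr) nrow(tr$reaches), 0L))
  cat(sprintf("<reach_session> %d trials, %d reaches", n, nr))
  if (!is.na(x$mouse_id)) cat(sprintf(", mouse %s", x$mouse_id))
  cat("\n")
  invisible(x)
}

#' @export
length.reach_session <- function(x) length(x$trials)

#' Analysis windows relative to cue onset
#'
#' Defines every time window used by the behavioral statistics, in seconds
#' relative to cue onset. Windows are half-open `[start, end)` except
#' `uncued_reach_window`, which is closed (reaches "between 3.5 s and 7 s"
#' after the cue).
#'
#' @param cued_window hit window for d-prime and the reinforcement shift.
#' @param uncued_window pre-cue window for the reinforcement shift.
#' @param fa_window_1 first false-alarm window.
#' @param fa_window_2 second false-alarm window.
#' @param cued_reach_max latest cued-outcome reach, seconds after cue.
#' @param post_cue_exclusion no-reach window required for uncued trial types.
#' @param uncued_reach_window closed window for uncued outcomes.
#' @return an object of class `"window_spec"`.
#' @export
window_spec <- function(cued_window = c(0, 0.4),
                        uncued_window = c(-3.0, -0.25),
                        fa_window_1 = c(-0.4, 0),
                        fa_window_2 = c(-1.0, -0.6),
                        cued_reach_max = 1.0,
                        post_cue_exclusion = 1.5,
                        uncued_reach_window = c(3.5, 7.0)) {
  chk <- function(w) stopifnot(length(w) == 2L, w[1] < w[2])
  chk(cued_window); chk(uncued_window); chk(fa_window_1); chk(fa_window_2)
  chk(uncued_reach_window)
  stopifnot(cued_reach_max > 0, post_cue_exclusion > 0)
  structure(list(cued_window = cued_window, uncued_window = uncued_window,
                 fa_window_1 = fa_window_1, fa_window_2 = fa_window_2,
                 cued_reach_max = cued_reach_max,
                 post_cue_exclusion = post_cue_exclusion,
                 uncued_reach_window = uncued_reach_window),
            class = "window_spec")
}

# times of reaches relative to this trial's cue
.rel_reach_times <- function(tr) {
  if (!tr$cue_present || !nrow(tr$reaches)) return(numeric())
  tr$reaches$t_arm - tr$t_cue
}

# half-open window membership [a, b)
.in_half_open <- function(t, w) t >= w[1] & t < w[2]

# closed window membership [a, b]
.in_closed <- function(t, w) t >= w[1] & t <= w[2]

#' All reach times of a session (session clock)
#' @param session a [reach_session()].
#' @return numeric vector, sorted.
#' @export
session_reach_times <- function(session) {
  sort(unlist(lapply(session$trials, function(tr) tr$reaches$t_arm),
              use.names = FALSE))
}

#' Cue onset times of a session
#' @param session a [reach_session()].
#' @return numeric vector (cue trials only), sorted.
#' @export
session_cue_times <- function(session) {
  tc <- vapply(session$trials, `[[`, 0, "t_cue")
  sort(tc[!is.na(tc)])
}
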