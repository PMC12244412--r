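#' Configuration for the synthetic behavioral session generator
#'
#' Defaults reproduce the automated-rig trial structure: a 250-ms cue, the
#' pellet withdrawn 8 s after cue onset, a two-part inter-trial interval
#' (uniform 0--3.5 s, then with probability 0.7 an additional uniform
#' 9.5--13 s), 30% pellet occupancy on non-catch trials, 10% catch trials
#' (cue on, pellet deliberately omitted), and a baseline reach rate of
#' about 0.25 Hz.
#'
#' Reaching is an inhomogeneous Poisson process. In the 400-ms cued window
#' the rate is `baseline_rate * cue_gain` plus a cued reinforcement state;
#' elsewhere it is `baseline_rate` plus an uncued reinforcement state. A
#' cued success on trial n increments the cued state by
#' `reinforcement_delta` on trial n+1 (uncued successes increment the
#' uncued state); both states decay geometrically with half-life
#' `decay_half_life` trials.
#'
#' @param baseline_rate spontaneous reach rate, Hz.
#' @param cue_gain multiplicative rate gain in the cued window (1 = naive).
#' @param reinforcement_delta Hz added to the next trial's cued (resp.
#'   uncued) rate after a cued (resp. uncued) success.
#' @param decay_half_life half-life of the reinforcement state, trials.
#' @param catch_prob probability a cue trial is a catch trial.
#' @param pellet_occupancy probability a non-catch trial has a pellet.
#' @param cue_duration_s cue duration, seconds.
#' @param pellet_retract_s pellet withdrawn this long after cue onset.
#' @param iti_uniform_max_s upper bound of the first (uniform) ITI part.
#' @param iti_continue_prob probability the ITI continues into part two.
#' @param iti_extra_s range (length 2) of the additional ITI, seconds.
#' @param success_prob_given_pellet probability a reach with the pellet
#'   available is successful (otherwise it is a drop).
#' @param pre_cue_lead_s pellet-advance plus delay time from trial start
#'   to cue onset, seconds.
#' @param n_trials number of trials.
#' @param inhibition_schedule `NULL`, or a function `(trial index) ->
#'   NULL | c(start, end)` giving the inhibition window relative to cue
#'   onset, or the string `"interleaved"` for a random half of trials
#'   inhibited for 1 s from 5 ms before the cue.
#' @param inhibition_gates_update if `TRUE`, the reinforcement update after
#'   a cued success is abolished when inhibition overlaps the outcome
#'   reach (used to plant a causal role for inhibition).
#' @param inhibition_gate_span seconds after the reach during which
#'   inhibition overlap abolishes the update.
#' @return list of class `"behavior_gen_config"`.
#' @export
behavior_gen_config <- function(baseline_rate = 0.25, cue_gain = 1,
                                reinforcement_delta = 0,
                                decay_half_life = 1,
                                catch_prob = 0.10, pellet_occupancy = 0.30,
                                cue_duration_s = 0.25, pellet_retract_s = 8.0,
                                iti_uniform_max_s = 3.5,
                                iti_continue_prob = 0.70,
                                iti_extra_s = c(9.5, 13),
                                success_prob_given_pellet = 0.85,
                                pre_cue_lead_s = 1.5,
                                n_trials = 150,
                                inhibition_schedule = NULL,
                                inhibition_gates_update = FALSE,
                                inhibition_gate_span = 0.5) {
  probs <- c(catch_prob, pellet_occupancy, iti_continue_prob,
             success_prob_given_pellet)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(baseline_rate >= 0, cue_gain >= 0, decay_half_life > 0,
            iti_extra_s[1] <= iti_extra_s[2], n_trials >= 1)
  structure(as.list(environment()), class = "behavior_gen_config")
}

# piecewise-constant inhomogeneous Poisson draw on [t0, t1) at `rate`
.draw_poisson_interval <- function(t0, t1, rate) {
  if (rate <= 0 || t1 <= t0) return(numeric())
  n <- stats::rpois(1, rate * (t1 - t0))
  if (!n) return(numeric())
  sort(stats::runif(n, t0, t1))
}

#' Generate a synthetic behavioral session
#'
#' Draws a session from the trial-structure and reinforcement model in
#' [behavior_gen_config()], returning the session together with the
#' planted truth (per-trial reinforcement states, pellet and catch flags,
#' and the generator's own trial classification).
#'
#' @param cfg a [behavior_gen_config()].
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param mouse_id,session_id optional identifiers.
#' @return list with elements `session` (a [reach_session()]) and `truth`
#'   (a list with `config`, `seed`, per-trial data.frame `trials`, and
#'   `n_rate_floor_warnings`).
#' @export
generate_session <- function(cfg = behavior_gen_config(), seed = 1L,
                             mouse_id = "sim", session_id = "sim-1") {
  stopifnot(inherits(cfg, "behavior_gen_config"))
  set.seed(seed)
  n <- cfg$n_trials
  decay <- 2^(-1 / cfg$decay_half_life)
  s_cued <- 0
  s_uncued <- 0
  t_now <- 0
  floor_warn <- 0L
  trials <- vector("list", n)
  truth <- vector("list", n)

  inh_fun <- cfg$inhibition_schedule
  if (is.character(inh_fun) && identical(inh_fun, "interleaved")) {
    inh_on <- sample(rep(c(TRUE, FALSE), length.out = n))
    inh_fun <- function(i) if (inh_on[i]) c(-0.005, 0.995) else NULL
  }

  for (i in seq_len(n)) {
    iti <- stats::runif(1, 0, cfg$iti_uniform_max_s)
    if (stats::runif(1) < cfg$iti_continue_prob) {
      iti <- iti + stats::runif(1, cfg$iti_extra_s[1], cfg$iti_extra_s[2])
    }
    trial_start <- t_now
    t_cue <- trial_start + iti + cfg$pre_cue_lead_s
    trial_end <- t_cue + cfg$pellet_retract_s + 0.5

    is_catch <- stats::runif(1) < cfg$catch_prob
    pellet <- !is_catch && stats::runif(1) < cfg$pellet_occupancy

    r_cued <- cfg$baseline_rate * cfg$cue_gain + s_cued
    r_uncued <- cfg$baseline_rate + s_uncued
    if (r_cued < 0) { r_cued <- 0; floor_warn <- floor_warn + 1L }
    if (r_uncued < 0) { r_uncued <- 0; floor_warn <- floor_warn + 1L }

    cw <- t_cue + c(0, 0.4)
    t_arm <- c(.draw_poisson_interval(trial_start, cw[1], r_uncued),
               .draw_poisson_interval(cw[1], cw[2], r_cued),
               .draw_poisson_interval(cw[2], trial_end, r_uncued))
    t_arm <- sort(t_arm)

    # outcomes: the pellet is reachable from cue onset until retraction,
    # and is dislodged by the first reach that touches it
    pellet_there <- pellet
    outcome <- character(length(t_arm))
    for (k in seq_along(t_arm)) {
      avail <- pellet_there && t_arm[k] >= t_cue &&
        t_arm[k] < t_cue + cfg$pellet_retract_s
      if (avail) {
        ok <- stats::runif(1) < cfg$success_prob_given_pellet
        outcome[k] <- if (ok) "success" else "drop"
        pellet_there <- FALSE
      } else {
        outcome[k] <- "pellet_missing"
      }
    }

    inh_rel <- if (is.function(inh_fun)) inh_fun(i) else NULL
    inh_abs <- if (!is.null(inh_rel)) t_cue + inh_rel else NULL
    if (!is.null(inh_abs)) {
      inh_abs[1] <- max(inh_abs[1], trial_start)
      inh_abs[2] <- min(inh_abs[2], trial_end)
    }

    tr <- trial(trial_start, trial_end, t_cue = t_cue, cue_present = TRUE,
                pellet_presented = pellet, catch = is_catch,
                inhibition_window = inh_abs,
                reaches = reaches(t_arm, outcome), trial_id = i - 1L)
    trials[[i]] <- tr
    cls <- classify_trial(tr)

    # reinforcement update for trial i + 1
    s_cued <- s_cued * decay
    s_uncued <- s_uncued * decay
    gated <- FALSE
    if (cls %in% c("cued_success", "uncued_success")) {
      t_out <- if (cls == "cued_success") {
        t_arm[outcome == "success" & t_arm >= t_cue][1]
      } else {
        t_arm[outcome == "success"][1]
      }
      if (cfg$inhibition_gates_update && !is.null(inh_abs) &&
          cls == "cued_success") {
        gated <- inh_abs[1] < t_out + cfg$inhibition_gate_span &&
          inh_abs[2] > t_out
      }
      if (!gated) {
        if (cls == "cued_success") s_cued <- s_cued + cfg$reinforcement_delta
        if (cls == "uncued_success") s_uncued <- s_uncued + cfg$reinforcement_delta
      }
    }

    truth[[i]] <- data.frame(trial_id = i - 1L, class = cls,
                             pellet = pellet, catch = is_catch,
                             s_cued = r_cued - cfg$baseline_rate * cfg$cue_gain,
                             s_uncued = r_uncued - cfg$baseline_rate,
                             update_gated = gated)
    t_now <- trial_end
  }

  list(session = reach_session(trials, mouse_id = mouse_id,
                               session_id = session_id),
       truth = list(config = cfg, seed = seed,
                    trials = do.call(rbind, truth),
                    n_rate_floor_warnings = floor_warn))
}
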