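# Hand-built fixtures used across test files. Everything is generated in
# code; no data files.

# one cue trial with given relative reach times/outcomes; cue 4 s into
# the trial so the uncued and false-alarm windows fit inside it
make_trial <- function(rel_times = numeric(), outcomes = character(),
                       t0 = 0, cue_at = 4, trial_len = 13,
                       cue_present = TRUE, pellet = TRUE,
                       chewing = FALSE, inhibition_rel = NULL,
                       trial_id = NA_integer_) {
  t_cue <- t0 + cue_at
  trial(
    trial_start = t0, trial_end = t0 + trial_len,
    t_cue = if (cue_present) t_cue else NA_real_,
    cue_present = cue_present, pellet_presented = pellet,
    chewing_at_start = chewing,
    inhibition_window = if (!is.null(inhibition_rel)) t_cue + inhibition_rel,
    reaches = reaches(t_cue + rel_times, outcomes),
    trial_id = trial_id
  )
}

# session built from a vector of per-trial recipes; each recipe is a list
# with rel/out (+ optional chewing, inhibition_rel, pellet)
make_session <- function(recipes, trial_len = 13) {
  trials <- vector("list", length(recipes))
  t0 <- 0
  for (i in seq_along(recipes)) {
    r <- recipes[[i]]
    trials[[i]] <- make_trial(
      rel_times = r$rel %||% numeric(),
      outcomes = r$out %||% character(),
      t0 = t0, trial_len = trial_len,
      pellet = r$pellet %||% TRUE,
      chewing = isTRUE(r$chewing),
      inhibition_rel = r$inhibition_rel,
      trial_id = i - 1L
    )
    t0 <- t0 + trial_len
  }
  reach_session(trials)
}

# session with n_per trials of each of the four classes, interleaved;
# reach times are jittered (seeded) so event channels decorrelate, which
# matters for GLM identifiability
make_balanced_session <- function(n_per = 25, trial_len = 13, seed = 99) {
  set.seed(seed)
  recipes <- list()
  for (i in seq_len(n_per)) {
    recipes <- c(recipes, list(
      list(rel = runif(1, 0.05, 0.9), out = "success"),
      list(rel = runif(1, 0.05, 0.9), out = "drop"),
      list(rel = runif(1, 3.6, 6.9), out = "success"),
      list(rel = runif(1, 3.6, 6.9), out = "drop")
    ))
  }
  recipes <- sample(recipes)
  make_session(recipes, trial_len = trial_len)
}

# trials_df (t_arm, condition, trial_id) for the neural modules
balanced_trials_df <- function(session, spec = window_spec()) {
  cls <- classify_session(session, spec)
  keep <- cls %in% trial_classes
  ta <- vapply(which(keep), function(i) {
    outcome_reach_time(session$trials[[i]], cls[i], spec)
  }, 0)
  data.frame(
    trial_id = vapply(session$trials, `[[`, 0L, "trial_id")[keep],
    condition = vapply(cls[keep], cuedreach:::map_class_to_condition, ""),
    t_arm = ta
  )
}

# "trained-stage" generator configuration: paper-pinned structure
# (occupancy, catch, ITI mixture) with a strong cue response and low
# spontaneous baseline so cued successes occur at useful frequency
trained_config <- function(...) {
  behavior_gen_config(baseline_rate = 0.1, cue_gain = 30,
                      success_prob_given_pellet = 0.85, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
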