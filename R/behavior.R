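#' Classify the behavioral experience of a trial
#'
#' Assigns each cue trial to one of four behavioral classes used throughout
#' the trial-to-trial analyses, or `"other"` when none applies:
#'
#' * `cued_success` -- no reach before the cue, and the first reach within
#'   `cued_reach_max` (1 s) of cue onset was a success.
#' * `cued_failure` -- no reach before the cue, and the first reach within
#'   1 s of cue onset was a failure.
#' * `uncued_success` -- no reach before the cue, no reach within the
#'   1.5-s post-cue exclusion window, and a successful reach between 3.5 s
#'   and 7 s after the cue.
#' * `uncued_failure` -- either a failed reach before the cue (with the
#'   mouse not chewing at trial start) or a failed reach between 3.5 s and
#'   7 s after the cue, with no reach in the 1.5-s post-cue window and no
#'   successful reach anywhere in the trial.
#'
#' Cue-omission trials return `"other"`.
#'
#' @param tr a [trial()].
#' @param spec a [window_spec()].
#' @param pre_cue_rule how "did not reach before the cue" is evaluated:
#'   the full pre-cue span of the trial (default) or only the uncued
#'   window of `spec`.
#' @return one of `"cued_success"`, `"cued_failure"`, `"uncued_success"`,
#'   `"uncued_failure"`, `"other"`.
#' @export
classify_trial <- function(tr, spec = window_spec(),
                           pre_cue_rule = c("full_span", "uncued_window")) {
  stopifnot(inherits(tr, "reach_trial"), inherits(spec, "window_spec"))
  pre_cue_rule <- match.arg(pre_cue_rule)
  if (!tr$cue_present) return("other")
  if (nrow(tr$reaches) && is.unsorted(tr$reaches$t_arm, strictly = TRUE)) {
    stop("invalid input: reach times must be strictly increasing")
  }
  rel <- .rel_reach_times(tr)
  out <- tr$reaches$outcome

  pre <- if (pre_cue_rule == "full_span") {
    rel < 0
  } else {
    .in_half_open(rel, spec$uncued_window)
  }
  no_pre <- !any(pre)

  in_cued <- .in_half_open(rel, c(0, spec$cued_reach_max))
  if (no_pre && any(in_cued)) {
    first <- which(in_cued)[1L]
    return(if (out[first] == "success") "cued_success" else "cued_failure")
  }

  no_post_cue <- !any(.in_half_open(rel, c(0, spec$post_cue_exclusion)))
  in_unc <- .in_closed(rel, spec$uncued_reach_window)

  if (no_pre && no_post_cue && any(in_unc & out == "success")) {
    return("uncued_success")
  }

  pre_fail <- any(pre & is_failure(out)) && !tr$chewing_at_start
  unc_fail <- any(in_unc & is_failure(out))
  no_success <- !any(out == "success")
  if ((pre_fail || unc_fail) && no_post_cue && no_success) {
    return("uncued_failure")
  }
  "other"
}

#' Classify every trial of a session
#'
#' @param session a [reach_session()] (or list of trials).
#' @inheritParams classify_trial
#' @return character vector of trial classes, one per trial.
#' @export
classify_session <- function(session, spec = window_spec(),
                             pre_cue_rule = c("full_span", "uncued_window")) {
  trials <- if (inherits(session, "reach_session")) session$trials else session
  pre_cue_rule <- match.arg(pre_cue_rule)
  vapply(trials, classify_trial, "", spec = spec, pre_cue_rule = pre_cue_rule)
}

# Per-trial reach counts in a cue-relative window, counting every session
# reach (windows may extend beyond trial boundaries into the ITI).
.window_counts <- function(trials, window, reach_times = NULL) {
  if (is.null(reach_times)) {
    reach_times <- sort(unlist(lapply(trials, function(tr) tr$reaches$t_arm),
                               use.names = FALSE))
  }
  vapply(trials, function(tr) {
    if (!tr$cue_present) return(NA_real_)
    rel <- reach_times - tr$t_cue
    sum(.in_half_open(rel, window))
  }, 0)
}

#' Mean reach rate in a cue-relative window
#'
#' The rate estimator behind the reach-rate learning curves and the
#' two-dimensional reinforcement-shift analysis: the mean over cue trials
#' of (reach count in window) / (window duration). All session reaches are
#' counted, so windows may extend before the trial boundary into the ITI.
#'
#' @param trials a [reach_session()] or list of [trial()] objects; all must
#'   be cue trials.
#' @param window numeric length-2, seconds relative to cue onset,
#'   half-open `[start, end)`.
#' @param reach_times optional pre-extracted vector of session reach times.
#' @return rate in Hz.
#' @export
window_reach_rate <- function(trials, window, reach_times = NULL) {
  if (inherits(trials, "reach_session")) trials <- trials$trials
  if (!length(trials)) stop("no trials supplied")
  stopifnot(length(window) == 2L, diff(window) > 0)
  counts <- .window_counts(trials, window, reach_times)
  if (anyNA(counts)) stop("all trials must be cue trials")
  mean(counts) / diff(window)
}

# clip a proportion away from {0, 1} before the normal-quantile transform;
# saturated rates are replaced with 1/(2n) resp. 1 - 1/(2n)
.clip_rate <- function(p, n) {
  pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
}

#' Behavioral discriminability index d'
#'
#' `d' = z(hit) - z(FA)`, where the hit rate is the fraction of cue trials
#' with one or more reaches in the 400-ms window after cue onset and the
#' false-alarm rate is the analogous fraction for a pre-cue window, both
#' passed through the standard-normal quantile function. Under
#' `variant = "dual_fa_min"` two false-alarm windows are used (0.4 s and
#' 1 s before the cue) and the lower of the two candidate d' values is
#' reported, so that preemptive reaching anywhere shortly before the cue
#' depresses d'. `variant = "single_fa"` uses only the first window.
#'
#' Saturated rates are clipped to `1/(2n)` and `1 - 1/(2n)` before the
#' quantile transform.
#'
#' @param trials a [reach_session()] or list of [trial()] objects.
#' @param spec a [window_spec()].
#' @param variant `"dual_fa_min"` or `"single_fa"`.
#' @return a list of class `"dprime_result"` with elements `dprime`,
#'   `hit_rate`, `fa_rates`, `n_trials`.
#' @export
dprime <- function(trials, spec = window_spec(),
                   variant = c("dual_fa_min", "single_fa")) {
  if (inherits(trials, "reach_session")) trials <- trials$trials
  variant <- match.arg(variant)
  trials <- Filter(function(tr) tr$cue_present, trials)
  n <- length(trials)
  if (!n) stop("d-prime requires at least one cue trial")
  reach_times <- sort(unlist(lapply(trials, function(tr) tr$reaches$t_arm),
                             use.names = FALSE))
  frac_with_reach <- function(window) {
    mean(.window_counts(trials, window, reach_times) >= 1)
  }
  hit <- frac_with_reach(spec$cued_window)
  fa1 <- frac_with_reach(spec$fa_window_1)
  z <- function(p) stats::qnorm(.clip_rate(p, n))
  if (variant == "single_fa") {
    d <- z(hit) - z(fa1)
    fa <- fa1
  } else {
    fa2 <- frac_with_reach(spec$fa_window_2)
    d <- min(z(hit) - z(fa1), z(hit) - z(fa2))
    fa <- c(fa1, fa2)
  }
  structure(list(dprime = d, hit_rate = hit, fa_rates = fa, n_trials = n),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %.3f (hit %.3f, FA %s, n = %d)\n", x$dprime, x$hit_rate,
              paste(sprintf("%.3f", x$fa_rates), collapse = "/"), x$n_trials))
  invisible(x)
}

#' Learning stage from d'
#'
#' Beginner: d' < 0.25; intermediate: 0.25 <= d' < 0.75; expert: d' >= 0.75.
#'
#' @param d numeric vector of d' values (finite).
#' @return character vector of stages.
#' @export
learning_stage <- function(d) {
  if (any(!is.finite(d))) stop("d' must be finite")
  ifelse(d < 0.25, "beginner", ifelse(d < 0.75, "intermediate", "expert"))
}

#' Did the mouse improve within the session?
#'
#' Splits the ordered trials three ways -- last 75% vs first 25%, halves,
#' and last 25% vs first 75% -- computes d' on each segment, and flags the
#' session as learned if any of the three contrasts exceeds 0.1 (strictly).
#'
#' @param trials ordered [reach_session()] or list of trials.
#' @param spec a [window_spec()].
#' @param variant d' variant, see [dprime()].
#' @return list of class `"session_learned_flags"` with `delta_d1`,
#'   `delta_d2`, `delta_d3`, `learned`.
#' @export
session_learned <- function(trials, spec = window_spec(),
                            variant = c("dual_fa_min", "single_fa")) {
  if (inherits(trials, "reach_session")) trials <- trials$trials
  variant <- match.arg(variant)
  n <- length(trials)
  k25 <- floor(0.25 * n)
  k50 <- floor(0.50 * n)
  k75 <- floor(0.75 * n)
  if (k25 < 1L || k75 >= n) stop("too few trials to split the session")
  d_of <- function(idx) dprime(trials[idx], spec, variant)$dprime
  d1 <- d_of((k25 + 1L):n) - d_of(1:k25)
  d2 <- d_of((k50 + 1L):n) - d_of(1:k50)
  d3 <- d_of((k75 + 1L):n) - d_of(1:k75)
  structure(list(delta_d1 = d1, delta_d2 = d2, delta_d3 = d3,
                 learned = max(d1, d2, d3) > 0.1),
            class = "session_learned_flags")
}

#' Select new learning days for one mouse
#'
#' A new learning day is a pre-expert session (d' < 0.75) whose d' strictly
#' exceeds the d' achieved by that mouse on every previous day. The last
#' 10% of trials in each session are discarded before computing d', because
#' mice disengage late in the session.
#'
#' @param sessions an ordered list of [reach_session()] objects for one
#'   mouse, or a numeric vector of per-day d' values (assumed already
#'   computed with the late-trial discard).
#' @param spec a [window_spec()].
#' @param variant d' variant, see [dprime()].
#' @param expert_threshold d' at and above which days are excluded.
#' @param discard_frac fraction of trials discarded at session end.
#' @return integer vector of day indices (1-based).
#' @export
new_learning_days <- function(sessions, spec = window_spec(),
                              variant = c("dual_fa_min", "single_fa"),
                              expert_threshold = 0.75, discard_frac = 0.10) {
  variant <- match.arg(variant)
  if (is.numeric(sessions)) {
    d <- sessions
  } else {
    stopifnot(length(sessions) >= 1L)
    d <- vapply(sessions, function(s) {
      trials <- if (inherits(s, "reach_session")) s$trials else s
      keep <- seq_len(max(1L, length(trials) - floor(discard_frac * length(trials))))
      dprime(trials[keep], spec, variant)$dprime
    }, 0)
  }
  if (!length(d)) return(integer())
  run_max <- c(-Inf, cummax(d)[-length(d)])
  which(d < expert_threshold & d > run_max)
}

#' Probability that a reach was preceded (or followed) by the cue
#'
#' The fraction of reaches with a cue onset within `window_s` before
#' (direction `"preceded"`) or after (direction `"followed"`) the reach,
#' with the binomial standard deviation `sqrt(p (1 - p) / n)`.
#'
#' @param session a [reach_session()] or list of trials.
#' @param window_s window length in seconds (default 0.4).
#' @param direction `"preceded"` or `"followed"`.
#' @return list with `p`, `sd`, `n_reaches`.
#' @export
p_cue_given_reach <- function(session, window_s = 0.4,
                              direction = c("preceded", "followed")) {
  direction <- match.arg(direction)
  trials <- if (inherits(session, "reach_session")) session$trials else session
  reach_t <- sort(unlist(lapply(trials, function(tr) tr$reaches$t_arm),
                         use.names = FALSE))
  cue_t <- vapply(trials, `[[`, 0, "t_cue")
  cue_t <- sort(cue_t[!is.na(cue_t)])
  n <- length(reach_t)
  if (!n) stop("no reaches in session")
  hit <- vapply(reach_t, function(tr) {
    if (direction == "preceded") {
      any(cue_t <= tr & cue_t > tr - window_s)
    } else {
      any(cue_t >= tr & cue_t < tr + window_s)
    }
  }, TRUE)
  p <- mean(hit)
  list(p = p, sd = sqrt(p * (1 - p) / n), n_reaches = n)
}

#' Time of the class-defining outcome reach of a trial
#'
#' For cued classes, the first reach within 1 s of the cue; for uncued
#' success, the first successful reach in the 3.5--7-s window; for uncued
#' failure, the first qualifying failed reach (pre-cue, or in the
#' 3.5--7-s window). Used to align neural and photometry analyses on the
#' moment the outcome became known.
#'
#' @param tr a [trial()].
#' @param class the trial's class from [classify_trial()].
#' @param spec a [window_spec()].
#' @return reach time in seconds (session clock), or `NA` for `"other"`.
#' @export
outcome_reach_time <- function(tr, class, spec = window_spec()) {
  if (class == "other" || !nrow(tr$reaches)) return(NA_real_)
  rel <- .rel_reach_times(tr)
  out <- tr$reaches$outcome
  idx <- switch(class,
    cued_success = ,
    cued_failure = which(.in_half_open(rel, c(0, spec$cued_reach_max)))[1],
    uncued_success = which(.in_closed(rel, spec$uncued_reach_window) &
                             out == "success")[1],
    uncued_failure = {
      cand <- which((rel < 0 | .in_closed(rel, spec$uncued_reach_window)) &
                      is_failure(out))
      if (length(cand)) cand[1] else NA_integer_
    })
  if (is.na(idx)) NA_real_ else tr$reaches$t_arm[idx]
}

#' Two-proportion Z-test
#'
#' Pooled-proportion z statistic and two-sided p value for comparing
#' `k1/n1` against `k2/n2`.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `z`, `p`, and the two sample proportions.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0)
  if (k1 > n1 || k2 > n2) stop("k must not exceed n")
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Mixed-effects condition contrast
#'
#' Fits `metric ~ condition + (1 | mouse)`: an overall intercept, a fixed
#' condition effect, and a Gaussian random intercept per mouse to absorb
#' baseline differences between animals. With a single mouse the model is
#' degenerate and an ordinary linear regression is fitted instead, with a
#' warning.
#'
#' @param data a data.frame with columns `mouse`, `condition` (two levels
#'   or 0/1) and `value`.
#' @return list of class `"condition_mixed_model"` with `beta0`, `beta1`,
#'   `sigma_u2` (random-intercept variance), `sigma_e2` (residual
#'   variance), `p_value` (for the condition effect) and the fitted model.
#' @export
fit_condition_mixed_model <- function(data) {
  stopifnot(all(c("mouse", "condition", "value") %in% names(data)))
  data$condition <- as.numeric(factor(data$condition)) - 1
  if (length(unique(data$condition)) < 2L) {
    stop("both conditions must be represented")
  }
  if (length(unique(data$mouse)) < 2L) {
    warning("single mouse: falling back to ordinary linear regression")
    fit <- stats::lm(value ~ condition, data = data)
    co <- summary(fit)$coefficients
    return(structure(list(beta0 = co[1, 1], beta1 = co[2, 1],
                          sigma_u2 = 0, sigma_e2 = summary(fit)$sigma^2,
                          p_value = co[2, 4], model = fit),
                     class = "condition_mixed_model"))
  }
  fit <- lmerTest::lmer(value ~ condition + (1 | mouse), data = data)
  co <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(beta0 = co[1, 1], beta1 = co[2, 1],
                 sigma_u2 = vc$vcov[vc$grp == "mouse"],
                 sigma_e2 = vc$vcov[vc$grp == "Residual"],
                 p_value = co[2, "Pr(>|t|)"], model = fit),
            class = "condition_mixed_model")
}

#' Quality-control rules for session inclusion
#'
#' @param cheat_ratio exclude a session when its pre-cue (false-alarm
#'   window) reach rate exceeds `cheat_ratio` times its baseline
#'   (uncued-window) rate; the published analysis describes this judgment
#'   qualitatively, the default ratio of 2 makes it operational.
#' @param inhibition_alone_frac exclude a session when reaching evoked by
#'   inhibition alone (inhibition without cue) exceeds this fraction of
#'   the control cued reach rate (default 0.20).
#' @param min_baseline_hz floor on the baseline rate used in the cheat
#'   ratio, to avoid dividing by zero in quiet sessions.
#' @return list of class `"qc_rules"`.
#' @export
qc_rules <- function(cheat_ratio = 2, inhibition_alone_frac = 0.20,
                     min_baseline_hz = 0.02) {
  structure(list(cheat_ratio = cheat_ratio,
                 inhibition_alone_frac = inhibition_alone_frac,
                 min_baseline_hz = min_baseline_hz), class = "qc_rules")
}

#' Keep or exclude sessions by quality-control rules
#'
#' Two exclusion rules are applied. (1) Cheating: a session in which the
#' reach rate immediately before the cue exceeds `cheat_ratio` times the
#' spontaneous baseline (uncued-window rate) indicates the mouse detected
#' the approaching pellet without the cue. (2) Inhibition-alone reaching:
#' when trials with optogenetic inhibition but no cue show cued-window
#' reaching above `inhibition_alone_frac` of the control cued rate, the
#' inhibition itself has become a cue and the session is excluded.
#'
#' @param sessions list of [reach_session()] objects.
#' @param rules a [qc_rules()].
#' @param spec a [window_spec()].
#' @return data.frame with one row per session: `session`, `kept`,
#'   `reason` (`""` when kept).
#' @export
qc_filter_sessions <- function(sessions, rules = qc_rules(),
                               spec = window_spec()) {
  stopifnot(inherits(rules, "qc_rules"))
  res <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    trials <- s$trials
    cue_trials <- Filter(function(tr) tr$cue_present, trials)
    reason <- ""
    if (length(cue_trials)) {
      pre <- window_reach_rate(cue_trials, spec$fa_window_1)
      base <- max(window_reach_rate(cue_trials, spec$uncued_window),
                  rules$min_baseline_hz)
      if (pre > rules$cheat_ratio * base) {
        reason <- sprintf("cheating: pre-cue rate %.3f Hz > %.1fx baseline %.3f Hz",
                          pre, rules$cheat_ratio, base)
      }
    }
    if (reason == "") {
      inh_alone <- Filter(function(tr) {
        !tr$cue_present && !is.null(tr$inhibition_window)
      }, trials)
      ctrl <- Filter(function(tr) {
        tr$cue_present && is.null(tr$inhibition_window)
      }, trials)
      if (length(inh_alone) && length(ctrl)) {
        # rate in the 0.4-s window after inhibition onset, vs control cued rate
        w <- diff(spec$cued_window)
        inh_rate <- mean(vapply(inh_alone, function(tr) {
          t0 <- tr$inhibition_window[1]
          sum(tr$reaches$t_arm >= t0 & tr$reaches$t_arm < t0 + w) / w
        }, 0))
        ctrl_rate <- window_reach_rate(ctrl, spec$cued_window)
        if (ctrl_rate > 0 &&
            inh_rate > rules$inhibition_alone_frac * ctrl_rate) {
          reason <- sprintf(
            "inhibition-alone reaching %.3f Hz > %.0f%% of control cued rate %.3f Hz",
            inh_rate, 100 * rules$inhibition_alone_frac, ctrl_rate)
        }
      }
    }
    sid <- if (!is.na(s$session_id)) s$session_id else as.character(i)
    data.frame(session = sid, kept = reason == "", reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
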