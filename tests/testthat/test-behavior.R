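test_that("trial classification matches the four-class definitions", {
  spec <- window_spec()
  # success within 1 s of the cue, no pre-cue reach
  expect_equal(classify_trial(make_trial(0.5, "success"), spec),
               "cued_success")
  # first reach in the cued window decides the cued outcome
  expect_equal(classify_trial(make_trial(c(0.3, 0.8), c("drop", "success")),
                              spec), "cued_failure")
  # uncued success: quiet until 1.5 s, success between 3.5 and 7 s
  expect_equal(classify_trial(make_trial(5.0, "success"), spec),
               "uncued_success")
  # success at 2 s is outside every defined window
  expect_equal(classify_trial(make_trial(2.0, "success"), spec), "other")
  # pre-cue failure counts as uncued failure only without chewing
  expect_equal(classify_trial(make_trial(-1.0, "pellet_missing"), spec),
               "uncued_failure")
  expect_equal(classify_trial(make_trial(-1.0, "pellet_missing",
                                         chewing = TRUE), spec), "other")
  # a success anywhere in the trial vetoes uncued failure
  expect_equal(classify_trial(
    make_trial(c(-1.0, 7.5), c("drop", "success")), spec), "other")
  # late failed reach in the 3.5-7 s window
  expect_equal(classify_trial(make_trial(4.0, "drop"), spec),
               "uncued_failure")
  # cue-omission trials are never classified
  expect_equal(classify_trial(make_trial(0.5, "success",
                                         cue_present = FALSE), spec),
               "other")
})

test_that("classification is exclusive and order-invariant", {
  set.seed(11)
  spec <- window_spec()
  for (i in 1:40) {
    k <- sample(0:4, 1)
    rel <- sort(runif(k, -3.5, 8))
    out <- sample(reach_outcomes, k, replace = TRUE)
    tr <- make_trial(rel, out)
    cls <- classify_trial(tr, spec)
    expect_true(cls %in% c(trial_classes, "other"))
    # permuting the reach list (construction re-sorts) changes nothing
    if (k > 1) {
      perm <- sample(k)
      tr2 <- make_trial(rel[perm], out[perm])
      expect_identical(classify_trial(tr2, spec), cls)
    }
  }
})

test_that("window reach rate is the count/duration mean with linearity", {
  s <- make_session(rep(list(list(rel = 0.2, out = "success")), 10))
  expect_equal(window_reach_rate(s, c(0, 0.4)), 1 / 0.4)
  # zero case
  expect_equal(window_reach_rate(s, c(-2, -1)), 0)
  # doubling every count doubles the rate
  s2 <- make_session(rep(list(list(rel = c(0.1, 0.2),
                                   out = c("drop", "success"))), 10))
  expect_equal(window_reach_rate(s2, c(0, 0.4)),
               2 * window_reach_rate(s, c(0, 0.4)))
  expect_error(window_reach_rate(list(), c(0, 0.4)), "no trials")
})

test_that("d-prime matches the normal-quantile oracle", {
  # hit 841/1000 vs FA 500/1000: Phi^-1(0.841) - Phi^-1(0.5)
  mk <- function(n_hit, n_fa, n = 1000) {
    recipes <- lapply(seq_len(n), function(i) {
      rel <- c(if (i <= n_hit) 0.2, if (i <= n_fa) -0.2)
      if (length(rel)) list(rel = rel, out = rep("pellet_missing", length(rel)))
      else list()
    })
    make_session(recipes)
  }
  s <- mk(841, 500)
  d <- dprime(s, variant = "single_fa")
  expect_equal(d$hit_rate, 0.841)
  expect_equal(d$dprime, qnorm(0.841) - qnorm(0.5), tolerance = 1e-10)
  # symmetry: equal hit and FA rates give 0
  s0 <- mk(300, 300)
  expect_equal(dprime(s0, variant = "single_fa")$dprime, 0)
})

test_that("dual-FA variant reports the lower candidate", {
  # FA window 2 ([-1, -0.6)) busier than FA window 1 ([-0.4, 0))
  recipes <- lapply(1:100, function(i) {
    rel <- c(if (i <= 60) 0.2, if (i <= 10) -0.2, if (i <= 40) -0.8)
    if (length(rel)) list(rel = rel, out = rep("pellet_missing", length(rel)))
    else list()
  })
  s <- make_session(recipes)
  d_dual <- dprime(s, variant = "dual_fa_min")$dprime
  d1 <- qnorm(0.6) - qnorm(0.1)
  d2 <- qnorm(0.6) - qnorm(0.4)
  expect_equal(d_dual, min(d1, d2), tolerance = 1e-10)
  expect_lte(d_dual, d1)
  expect_lte(d_dual, d2)
})

test_that("d-prime is invariant to rate-preserving duplication and clips saturation", {
  recipes <- lapply(1:20, function(i) {
    if (i <= 12) list(rel = 0.2, out = "pellet_missing") else list()
  })
  s1 <- make_session(recipes)
  s2 <- make_session(c(recipes, recipes))
  d1 <- dprime(s1, variant = "single_fa")
  d2 <- dprime(s2, variant = "single_fa")
  expect_equal(d1$hit_rate, d2$hit_rate)
  # FA rate 0 is clipped to 1/(2n), which depends on n
  expect_equal(d1$dprime, qnorm(0.6) - qnorm(1 / 40))
  expect_equal(d2$dprime, qnorm(0.6) - qnorm(1 / 80))
})

test_that("learning stages use the 0.25 / 0.75 thresholds", {
  expect_equal(learning_stage(c(-0.1, 0.3, 0.75, 0.249, 0.25)),
               c("beginner", "intermediate", "expert", "beginner",
                 "intermediate"))
  expect_error(learning_stage(NaN), "finite")
})

test_that("session-learned flags follow the three-split > 0.1 rule", {
  # first half: no cued reaching; second half: strong cued reaching
  recipes <- c(
    lapply(1:40, function(i) list()),
    lapply(1:40, function(i) list(rel = 0.2, out = "success"))
  )
  fl <- session_learned(make_session(recipes))
  expect_true(fl$learned)
  expect_gt(max(fl$delta_d1, fl$delta_d2, fl$delta_d3), 0.1)
  # a flat session is not learned: hit and FA rates identical in every
  # segment (period-4 pattern aligned with the 25/50/75% boundaries)
  flat <- session_learned(make_session(lapply(1:80, function(i) {
    rel <- c(if (i %% 2 == 1) 0.2, if (i %% 4 %in% c(1, 2)) -0.2)
    if (length(rel)) list(rel = rel, out = rep("pellet_missing", length(rel)))
    else list()
  })))
  expect_false(flat$learned)
  expect_equal(max(flat$delta_d1, flat$delta_d2, flat$delta_d3), 0)
  expect_error(session_learned(make_session(list(list(), list()))),
               "too few")
})

test_that("new learning days track the strict running maximum below 0.75", {
  expect_equal(new_learning_days(c(0.1, 0.3, 0.2, 0.5)), c(1L, 2L, 4L))
  expect_equal(new_learning_days(c(0.5, 0.4, 0.3)), 1L)
  # a record day at or above 0.75 is excluded
  expect_equal(new_learning_days(c(0.1, 0.8, 0.85)), 1L)
  expect_equal(new_learning_days(numeric()), integer())
})

test_that("new learning days discard the final 10% of trials", {
  # last 8 of 80 trials carry all the cued reaching: discarded, so the
  # day's d' stays low and equals the no-reach session's d'
  recipes <- c(lapply(1:72, function(i) list()),
               lapply(1:8, function(i) list(rel = 0.2, out = "success")))
  s <- make_session(recipes)
  d_kept <- dprime(s$trials[1:72])$dprime
  got <- new_learning_days(list(s))
  expect_equal(got, if (d_kept < 0.75) 1L else integer())
  expect_equal(d_kept, 0)
})

test_that("P(cue | reach) matches saturation, monotonicity and the binomial SD", {
  s <- make_session(rep(list(list(rel = 0.1, out = "success")), 25))
  r <- p_cue_given_reach(s, 0.4, "preceded")
  expect_equal(r$p, 1)
  expect_equal(r$sd, 0)
  # wider windows can only raise the preceded probability
  s2 <- make_session(lapply(1:30, function(i) {
    list(rel = if (i %% 2) 0.1 else 1.0,
         out = if (i %% 2) "success" else "pellet_missing")
  }))
  p_narrow <- p_cue_given_reach(s2, 0.4, "preceded")$p
  p_wide <- p_cue_given_reach(s2, 1.5, "preceded")$p
  expect_gte(p_wide, p_narrow)
  expect_equal(p_cue_given_reach(s2, 0.4, "preceded")$sd,
               sqrt(p_narrow * (1 - p_narrow) / 30))
  expect_error(p_cue_given_reach(make_session(list(list(), list()))),
               "no reaches")
})

test_that("P(cue | reach) under Poisson reaching approaches the coverage fraction", {
  set.seed(21)
  cfg <- behavior_gen_config(n_trials = 400, cue_gain = 1)
  gen <- generate_session(cfg, seed = 77)
  r <- p_cue_given_reach(gen$session, 0.4, "preceded")
  # uniform reaching: P(cue within 0.4 s before a reach) ~ covered time
  dur <- max(vapply(gen$session$trials, `[[`, 0, "trial_end"))
  coverage <- length(session_cue_times(gen$session)) * 0.4 / dur
  expect_lt(abs(r$p - coverage), 4 * sqrt(coverage * (1 - coverage) / r$n_reaches) + 1e-3)
})

test_that("two-proportion z follows the pooled formula and is antisymmetric", {
  r <- two_proportion_z(48, 1000, 38, 1000)
  pool <- 86 / 2000
  z_hand <- (0.048 - 0.038) / sqrt(pool * (1 - pool) * (2 / 1000))
  expect_equal(r$z, z_hand, tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-abs(z_hand)), tolerance = 1e-12)
  r2 <- two_proportion_z(38, 1000, 48, 1000)
  expect_equal(r2$z, -r$z)
  expect_equal(r2$p, r$p)
  expect_equal(two_proportion_z(5, 50, 10, 100)$z, 0)
  expect_equal(two_proportion_z(5, 50, 10, 100)$p, 1)
  expect_error(two_proportion_z(11, 10, 5, 10), "exceed")
})

test_that("mixed model recovers the pooled slope when mice are exchangeable", {
  set.seed(31)
  dat <- data.frame(
    mouse = rep(sprintf("m%d", 1:6), each = 10),
    condition = rep(c(0, 1), 30),
    value = NA_real_
  )
  dat$value <- 1 + 0.8 * dat$condition + rnorm(60, 0, 0.3)
  fit <- fit_condition_mixed_model(dat)
  ols <- coef(lm(value ~ condition, dat))
  expect_equal(fit$beta1, unname(ols[2]), tolerance = 0.05)
  expect_gte(fit$sigma_u2, 0)
  expect_gt(fit$sigma_e2, 0)
  expect_lt(fit$p_value, 0.001)
  # translation shifts the intercept only
  dat2 <- dat; dat2$value <- dat2$value + 5
  fit2 <- fit_condition_mixed_model(dat2)
  expect_equal(fit2$beta1, fit$beta1, tolerance = 1e-6)
  expect_equal(fit2$beta0, fit$beta0 + 5, tolerance = 1e-6)
  # single mouse falls back with a warning
  expect_warning(fit_condition_mixed_model(dat[dat$mouse == "m1", ]),
                 "single mouse")
})

test_that("QC rules catch cheating and inhibition-alone reaching", {
  # clean session: kept
  clean <- make_session(lapply(1:40, function(i) {
    list(rel = 0.2, out = "success")
  }))
  res <- qc_filter_sessions(list(clean))
  expect_true(res$kept[1])
  # pre-cue rate 3x baseline with threshold 2: excluded
  cheat <- make_session(lapply(1:40, function(i) {
    list(rel = c(-2.5, -0.2), out = c("pellet_missing", "pellet_missing"))
  }))
  res2 <- qc_filter_sessions(list(cheat), qc_rules(cheat_ratio = 2))
  expect_false(res2$kept[1])
  expect_match(res2$reason[1], "cheating")
  # inhibition-alone reaching above 20% of the control cued rate
  recipes <- c(
    lapply(1:20, function(i) list(rel = 0.2, out = "success")),
    lapply(1:20, function(i) list(rel = 0.2, out = "pellet_missing"))
  )
  s <- make_session(recipes)
  for (i in 21:40) {
    tr <- s$trials[[i]]
    s$trials[[i]] <- trial(tr$trial_start, tr$trial_end, t_cue = NA,
                           cue_present = FALSE, pellet_presented = FALSE,
                           inhibition_window = tr$trial_start + c(4, 5),
                           reaches = tr$reaches, trial_id = tr$trial_id)
  }
  res3 <- qc_filter_sessions(list(s))
  expect_false(res3$kept[1])
  expect_match(res3$reason[1], "inhibition-alone")
})

test_that("null-cue sessions have d-prime centered on zero", {
  # cue gain 1, no reinforcement: mean d' over sessions within 3 SE of 0
  ds <- vapply(1:60, function(i) {
    gen <- generate_session(behavior_gen_config(n_trials = 60), seed = 1000 + i)
    dprime(gen$session, variant = "single_fa")$dprime
  }, 0)
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds)), 3 * se)
})
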