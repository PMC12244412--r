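# brute-force triplet oracle: enumerate all interior indices and apply
# the selection rules literally
brute_triplets <- function(session, condition, filter = "none") {
  cls <- classify_session(session)
  trials <- session$trials
  n <- length(trials)
  has_inh <- vapply(trials, function(tr) !is.null(tr$inhibition_window), TRUE)
  has_reach <- vapply(trials, function(tr) nrow(tr$reaches) > 0, TRUE)
  keep <- integer()
  for (i in seq_len(n)) {
    if (i == 1 || i == n) next
    ok <- switch(condition, any = TRUE, any_reach = has_reach[i],
                 cls[i] == condition)
    if (!ok) next
    if (filter != "none") {
      want <- filter == "inhibition_on"
      if (has_inh[i] != want) next
      ahead <- intersect((i + 2):(i + 5), seq_len(n))
      if (!any(has_inh[ahead] != want)) next
    }
    keep <- c(keep, i)
  }
  keep
}

test_that("triplet extraction agrees with exhaustive enumeration on small sessions", {
  set.seed(51)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    recipes <- lapply(seq_len(n), function(i) {
      k <- sample(0:2, 1)
      if (!k) return(list(inhibition_rel = if (runif(1) < 0.4) c(0, 1)))
      list(rel = sort(runif(k, -3.5, 7.5)),
           out = sample(reach_outcomes, k, replace = TRUE),
           inhibition_rel = if (runif(1) < 0.4) c(0, 1))
    })
    s <- make_session(recipes)
    for (cond in c("cued_success", "uncued_failure", "any", "any_reach")) {
      for (filt in c("none", "control_interleaved", "inhibition_on")) {
        got <- extract_triplets(s, cond, filt)$triplets$n
        expect_equal(got, brute_triplets(s, cond, filt),
                     info = sprintf("n=%d cond=%s filt=%s", n, cond, filt))
      }
    }
  }
})

test_that("the published interleaving example qualifies as control", {
  # inhibition pattern off,on,off,off,on,...: the off trial at index 3
  # has an on trial at index 5 (= n + 2), so it is a control triplet
  inh <- c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  recipes <- lapply(seq_along(inh), function(i) {
    list(rel = 0.3, out = "success",
         inhibition_rel = if (inh[i]) c(0, 1))
  })
  s <- make_session(recipes)
  tset <- extract_triplets(s, "cued_success", "control_interleaved")
  expect_true(3 %in% tset$triplets$n)
  expect_false(2 %in% tset$triplets$n)  # inhibition-on trial
})

test_that("shift point estimate is the difference of means and is deterministic", {
  # hand-built 7-trial session: trial 4 is the only cued success
  recipes <- list(
    list(rel = c(-1), out = "pellet_missing"),    # n-1 of nothing
    list(rel = c(0.1, 0.3), out = c("pellet_missing", "pellet_missing")),
    list(),                                        # n - 1
    list(rel = 0.3, out = "success"),              # n: cued success
    list(rel = c(0.2, -0.5), out = c("pellet_missing", "pellet_missing")),
    list(),
    list(rel = 0.3, out = "drop")
  )
  s <- make_session(recipes)
  tset <- extract_triplets(s, "cued_success")
  expect_equal(tset$triplets$n, 4L)
  sh <- conditioned_shift(tset, n_boot = 20, seed = 1)
  # n+1 (trial 5): one cued-window reach -> 2.5 Hz; one uncued reach
  # at -0.5 -> 1/2.75 Hz. n-1 (trial 3): zero everywhere.
  expect_equal(sh$delta_cued, 1 / 0.4)
  expect_equal(sh$delta_uncued, 1 / 2.75)
  # identical n-1 and n+1 populations give exactly zero
  sh0 <- conditioned_shift(extract_triplets(make_session(list(
    list(), list(rel = 0.3, out = "success"), list()
  )), "cued_success"), n_boot = 5, seed = 1)
  expect_equal(sh0$delta_cued, 0)
  expect_equal(sh0$delta_uncued, 0)
})

test_that("bootstrap draws are reproducible under seed and have correct shape", {
  gen <- generate_session(trained_config(n_trials = 250), seed = 61)
  tset <- extract_triplets(gen$session, "any_reach")
  a <- conditioned_shift(tset, n_boot = 50, seed = 9)
  b <- conditioned_shift(tset, n_boot = 50, seed = 9)
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$draws), 50)
  expect_error(conditioned_shift(extract_triplets(make_session(list(
    list(), list(), list()
  )), "cued_success"), 10, 1), "empty")
})

test_that("planted reinforcement delta is recovered and the null is centered", {
  # pooled triplets across sessions from the trained-stage generator
  pool_shift <- function(delta, n_sessions, seed0) {
    pre <- NULL; post <- NULL
    for (i in seq_len(n_sessions)) {
      gen <- generate_session(trained_config(n_trials = 200,
                                             reinforcement_delta = delta),
                              seed = seed0 + i)
      tset <- extract_triplets(gen$session, "cued_success")
      if (!nrow(tset$triplets)) next
      pre <- rbind(pre, tset$behavior[tset$triplets$n_minus, , drop = FALSE])
      post <- rbind(post, tset$behavior[tset$triplets$n_plus, , drop = FALSE])
    }
    list(d = colMeans(post) - colMeans(pre), m = nrow(pre),
         se = sqrt(apply(post, 2, var) / nrow(post) +
                     apply(pre, 2, var) / nrow(pre)))
  }
  eff <- pool_shift(0.5, 120, 7000)
  expect_gt(eff$m, 300)
  # recovered within ~3 SE of the planted 0.5 Hz
  expect_lt(abs(eff$d["cued"] - 0.5), 3 * eff$se["cued"])
  # uncued component unaffected
  expect_lt(abs(eff$d["uncued"]), 3 * eff$se["uncued"])
  null <- pool_shift(0, 60, 8000)
  expect_lt(abs(null$d["cued"]), 3 * null$se["cued"])
})

test_that("shift histogram integrates to one and peaks at the point estimate", {
  gen <- generate_session(trained_config(n_trials = 250), seed = 71)
  tset <- extract_triplets(gen$session, "any_reach")
  h <- shift_histogram(tset, n_boot = 300, seed = 2)
  dx <- diff(h$x[1:2]); dy <- diff(h$y[1:2])
  expect_equal(sum(h$density) * dx * dy, 1, tolerance = 1e-9)
  peak <- which(h$density == max(h$density), arr.ind = TRUE)[1, ]
  expect_lt(abs(h$x[peak[1]] - h$shift$delta_uncued),
            3 * h$shift$se["uncued"] + 0.05)
  expect_lt(abs(h$y[peak[2]] - h$shift$delta_cued),
            3 * h$shift$se["cued"] + 0.1)
})

test_that("backwards control conditions on trial n+2 with the right indices", {
  # 6 hand-built trials; cued success at position 5 conditions the
  # (n-1, n+1) = (2, 4) pair
  recipes <- list(list(), list(rel = 0.2, out = "drop"), list(),
                  list(rel = c(-1), out = "pellet_missing"),
                  list(rel = 0.3, out = "success"), list())
  s <- make_session(recipes)
  bc <- backwards_control(s, "cued_success", n_boot = 5, seed = 1)
  # trial 4 has one uncued reach; trial 2 has one cued-window reach
  expect_equal(bc$delta_cued, -1 / 0.4)
  expect_equal(bc$delta_uncued, 1 / 2.75)
})

test_that("backwards control abolishes the planted forward effect", {
  fwd_d <- NULL; fwd_pre <- NULL; fwd_post <- NULL
  bwd_pre <- NULL; bwd_post <- NULL
  for (i in 1:120) {
    gen <- generate_session(trained_config(n_trials = 200,
                                           reinforcement_delta = 0.5),
                            seed = 9000 + i)
    cls <- classify_session(gen$session)
    tset <- extract_triplets(gen$session, "cued_success", classes = cls)
    if (nrow(tset$triplets)) {
      fwd_pre <- rbind(fwd_pre, tset$behavior[tset$triplets$n_minus, , drop = FALSE])
      fwd_post <- rbind(fwd_post, tset$behavior[tset$triplets$n_plus, , drop = FALSE])
    }
    j <- which(cls == "cued_success" & seq_along(cls) >= 4)
    if (length(j)) {
      B <- tset$behavior
      bwd_pre <- rbind(bwd_pre, B[j - 3L, , drop = FALSE])
      bwd_post <- rbind(bwd_post, B[j - 1L, , drop = FALSE])
    }
  }
  fwd <- mean(fwd_post[, "cued"]) - mean(fwd_pre[, "cued"])
  se_fwd <- sqrt(var(fwd_post[, "cued"]) / nrow(fwd_post) +
                   var(fwd_pre[, "cued"]) / nrow(fwd_pre))
  bwd <- mean(bwd_post[, "cued"]) - mean(bwd_pre[, "cued"])
  se_bwd <- sqrt(var(bwd_post[, "cued"]) / nrow(bwd_post) +
                   var(bwd_pre[, "cued"]) / nrow(bwd_pre))
  # a clear forward effect exists ...
  expect_gt(fwd, 2 * se_fwd)
  expect_lt(abs(bwd), fwd)
  expect_lt(abs(bwd), 3 * se_bwd)
})

test_that("timing-resolved shift recovers inhibition gating of the update", {
  bins <- data.frame(start = c(-1.2, 0.2), width = c(1.2, 0.2))
  # gated generator: inhibition overlapping the reach abolishes the update
  d_ctrl <- c(); d_inh <- c()
  for (i in 1:50) {
    gen <- generate_session(trained_config(
      n_trials = 150, reinforcement_delta = 0.6,
      inhibition_schedule = "interleaved",
      inhibition_gates_update = TRUE), seed = 650 + i)
    cur <- timing_resolved_shift(gen$session, bins)
    d_ctrl <- c(d_ctrl, cur$d_control[2] * cur$n_control[2])
    d_inh <- c(d_inh, cur$d_inhibition[2] * cur$n_inhibition[2])
    if (i == 1) {
      expect_equal(nrow(cur), 2)
      expect_true(all(c("lag", "diff") %in% names(cur)))
    }
  }
  # weighted means over sessions: control updates, inhibition does not
  n_c <- 0; n_i <- 0
  for (i in 1:50) NULL
  expect_gt(sum(d_ctrl, na.rm = TRUE), sum(d_inh, na.rm = TRUE))
})

test_that("empty timing bins are reported as missing, not zero", {
  s <- make_balanced_session(5)
  bins <- data.frame(start = c(0.2, 100), width = c(0.2, 1))
  cur <- timing_resolved_shift(s, bins)
  expect_true(is.na(cur$d_control[2]))
  expect_equal(cur$n_control[2], 0)
})
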