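test_that("the condition tensor equals hand averages with the failure shift", {
  # 2 units, two trials per condition, hand-checkable spike patterns
  trials <- data.frame(
    t_arm = c(10, 30, 50, 70, 90, 110, 130, 150),
    condition = rep(tensor_conditions, each = 2)
  )
  # unit 1 fires 2 spikes in [0, 0.1) after every success-trial reach
  u1 <- sort(c(10.02, 10.05, 30.02, 30.05))
  # unit 2 fires 1 spike at +1.62 s on failure trials
  u2 <- c(50 + 1.62, 70 + 1.62)
  tt <- trial_tensor(list(u1, u2), trials, window = c(0, 5), bin_s = 0.1)
  expect_equal(dim(tt$responses), c(2, 8, 50))
  tensor <- build_tensor(tt, failure_shift_s = 0.77)
  expect_equal(tensor$shift_bins, 8)
  expect_equal(dim(tensor$data), c(2, 42, 4))
  # success slice, unit 1, first bin: 2 spikes / 0.1 s averaged over 2 trials
  expect_equal(tensor$data[1, 1, 1], 20)
  # failure impulse at bin 17 (1.6-1.7 s) lands at bin 17 - 8 = 9
  expect_equal(tensor$data[2, 9, 2], 10)
  expect_true(all(tensor$data[2, -9, 2] == 0))
  # unit firing identically in all conditions gives a constant slice
  trials_miss <- trials[trials$condition != "failure", ]
  expect_error(build_tensor(trial_tensor(list(u1), trials_miss)),
               "no trials")
})

test_that("the joint loading penalty matches hand evaluation on 3-neuron toys", {
  # disjoint unit loadings: num = 3 * |1 + 0|*2(pairs i<j counted once),
  # J = (1+1+1)/(1+1+1) = 1
  A <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(joint_loading_penalty(A), 1)
  # identical factors: denominator 0 -> Inf
  expect_equal(joint_loading_penalty(cbind(c(1, 2, 3), c(1, 2, 3))), Inf)
  # hand case: w = (2,1), (0,3), (1,1) ->
  # num = |2+1| + |0+3| + |1+1| = 8; den = |2-1| + |0-3| + |1-1| = 4
  A2 <- rbind(c(2, 1), c(0, 3), c(1, 1))
  expect_equal(joint_loading_penalty(A2), 2)
  # scale invariance and permutation invariance
  expect_equal(joint_loading_penalty(5 * A2), 2)
  expect_equal(joint_loading_penalty(A2[c(3, 1, 2), ]), 2)
  expect_equal(joint_loading_penalty(A2[, 2:1]), 2)
})

test_that("fitting an all-zero tensor yields uniform condition probabilities", {
  X <- array(0, dim = c(5, 10, 4))
  fit <- fit_kruskal_mnlr(X, R = 2,
                          cfg = kruskal_config(max_epochs = 500), seed = 1)
  P <- predict_kruskal(fit, X)
  expect_true(all(abs(P - 0.25) < 1e-6))
})

test_that("the optimizer fits planted structure with non-negative neuron factors", {
  set.seed(81)
  # planted rank-1 condition signal: one neuron group ramps on successes
  N <- 20; Tt <- 30
  X <- array(rnorm(N * Tt * 4, 0, 0.05), dim = c(N, Tt, 4))
  sig <- outer(c(rep(1, 10), rep(0, 10)), seq(0, 1, length.out = Tt))
  X[, , 1] <- X[, , 1] + 2 * sig
  X[, , 3] <- X[, , 3] + 2 * sig
  fit <- fit_kruskal_mnlr(X, R = 2,
                          cfg = kruskal_config(max_epochs = 6000), seed = 2)
  expect_true(all(fit$A >= 0))
  P <- predict_kruskal(fit, X)
  # success-like slices separate from failure-like slices
  expect_gt(P[1, "success"] + P[1, "cued_success"], 0.8)
  expect_gt(P[2, "failure"] + P[2, "cued_failure"], 0.8)
  expect_lt(fit$loss, 0.5)
  # reproducibility under seed
  fit2 <- fit_kruskal_mnlr(X, R = 2,
                           cfg = kruskal_config(max_epochs = 6000), seed = 2)
  expect_identical(fit$A, fit2$A)
  expect_identical(fit$loss, fit2$loss)
})

test_that("on exactly rank-1 data, rank 2 improves the loss only marginally", {
  set.seed(82)
  # noise-free rank-1 tensor: every factor score is proportional to the
  # per-condition amplitude, so extra components carry no usable signal
  N <- 12; Tt <- 20
  u <- runif(N); v <- sin(seq(0, pi, length.out = Tt))
  X <- array(0, dim = c(N, Tt, 4))
  for (k in 1:4) X[, , k] <- (0.5 * k) * outer(u, v)
  cfg <- kruskal_config(max_epochs = 6000)
  l1 <- min(vapply(1:3, function(s) {
    fit_kruskal_mnlr(X, 1, cfg, seed = s)$loss
  }, 0))
  l2 <- min(vapply(1:3, function(s) {
    fit_kruskal_mnlr(X, 2, cfg, seed = s)$loss
  }, 0))
  expect_lt(abs(l1 - l2), 0.05)
})

test_that("select_model picks the minimum-J run and concentrates planted groups", {
  # two disjoint planted neuron groups, planted through the spike
  # generator and averaged by the pipeline
  s <- make_balanced_session(40)
  sp <- generate_population_spikes(
    s, spike_gen_config(n_units = 24,
                        group_fractions = c(group1 = 0.5, group2 = 0.5,
                                            other = 0)), seed = 84)
  tensor <- build_tensor(trial_tensor(sp$units, balanced_trials_df(s)))
  sel <- select_model(tensor, ranks = 2, runs_per_rank = 5, chosen_rank = 2,
                      seed = 3)
  sub <- sel$diagnostics[sel$diagnostics$rank == 2, ]
  J_model <- joint_loading_penalty(sel$model$A)
  expect_equal(J_model, min(sub$J))
  # the min-J solution loads each planted group mostly on one factor
  g1 <- which(sp$truth$groups == "group1")
  g2 <- which(sp$truth$groups == "group2")
  mass <- function(rows) {
    m <- colSums(sel$model$A[rows, , drop = FALSE])
    max(m) / sum(m)
  }
  expect_gt(mass(g1), 0.8)
  expect_gt(mass(g2), 0.8)
  # the two groups prefer different factors
  f1 <- which.max(colSums(sel$model$A[g1, ]))
  f2 <- which.max(colSums(sel$model$A[g2, ]))
  expect_false(f1 == f2)
  expect_length(sel$component_weights, 2)
})

test_that("shuffle validation degrades prediction on planted two-group data", {
  s <- make_balanced_session(40)
  sp <- generate_population_spikes(s, spike_gen_config(n_units = 24),
                                   seed = 84)
  tdf <- balanced_trials_df(s)
  ids <- split(tdf$trial_id, tdf$condition)
  spl <- train_test_split(ids, seed = 5)
  train_ids <- unlist(lapply(spl, `[[`, "train"), use.names = FALSE)
  tt_train <- trial_tensor(sp$units, tdf[tdf$trial_id %in% train_ids, ])
  tt_test <- trial_tensor(sp$units, tdf[!tdf$trial_id %in% train_ids, ])
  fit <- fit_kruskal_mnlr(build_tensor(tt_train), R = 2,
                          cfg = kruskal_config(max_epochs = 6000), seed = 6)
  acc <- validate_shuffles(fit, tt_test, n_rep = 25, seed = 7)
  expect_gte(acc["real"], acc["shuffle_time"])
  expect_gt(acc["real"], acc["shuffle_both"] + 0.1)
  expect_gt(acc["real"], 0.8)
  # shuffling both axes leaves roughly chance performance
  expect_lt(acc["shuffle_both"], 0.75)
})
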