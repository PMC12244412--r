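test_that("the default design has 9 x 71 = 639 columns and correct placement", {
  d <- event_design()
  expect_equal(length(d$lags), 71)
  expect_equal(d$n_columns, 639)
  # two events with three lags give six columns
  d2 <- event_design(lag_range = c(-0.1, 0.1),
                     channels = c("cue", "reach"))
  ev <- list(cue = 5, reach = numeric())
  X2 <- build_design(ev, 20, d2)
  expect_equal(ncol(X2), 6)
  # single event at 10.0 s: the +0.5-lag column is 1 in the bin holding 10.5 s
  d3 <- event_design(lag_range = c(-0.5, 0.5), channels = "cue")
  X3 <- build_design(list(cue = 10.0), 20, d3)
  col <- X3[, which(abs(d3$lags - 0.5) < 1e-9)]
  expect_equal(which(col == 1), 1L + floor(10.5 / 0.1))
  expect_error(build_design(list(bogus = 1), 20), "unknown event")
  expect_error(build_design(list(cue = 30), 20), "within the session")
})

test_that("design construction is shift-equivariant", {
  d <- event_design(lag_range = c(-0.3, 0.4), channels = c("cue", "reach"))
  ev <- list(cue = c(3.02, 7.51), reach = c(4.2, 9.9))
  X1 <- build_design(ev, 40, d)
  k <- 17  # bins
  ev2 <- lapply(ev, function(tt) tt + k * d$bin_s)
  X2 <- build_design(ev2, 40 + k * d$bin_s, d)
  n <- nrow(X1)
  # overlap region: X2 shifted down by k bins equals X1
  expect_equal(as.matrix(X2[(k + 1):n, ]), as.matrix(X1[1:(n - k), ]),
               ignore_attr = TRUE)
})

test_that("r_squared matches hand arithmetic and edge cases", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  y <- c(2, 4, 9)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 1)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")
})

test_that("the alpha = 0 fit equals the normal-equations solution", {
  set.seed(61)
  # well-conditioned toy design: 2 channels, few lags, dense events
  d <- event_design(lag_range = c(-0.2, 0.3), channels = c("cue", "reach"))
  ev <- list(cue = sort(runif(40, 1, 99)), reach = sort(runif(30, 1, 99)))
  X <- build_design(ev, 100, d)
  beta_true <- rnorm(ncol(X))
  y <- as.numeric(X %*% beta_true) + rnorm(nrow(X), 0, 0.1)
  fit <- fit_glm(X, y, glm_config(alpha_grid = 0), design = d)
  n_test <- round(0.1 * nrow(X))
  tr <- seq_len(nrow(X) - n_test)
  Xc <- cbind(1, as.matrix(X[tr, ]))
  beta_hand <- solve(crossprod(Xc), crossprod(Xc, y[tr]))
  expect_equal(fit$intercept, beta_hand[1], tolerance = 1e-8)
  expect_equal(as.numeric(t(fit$coefficients)), beta_hand[-1],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$alpha, 0)
})

test_that("the sweep selects by held-out R-squared and never beats OLS dishonestly", {
  set.seed(62)
  d <- event_design(lag_range = c(-0.2, 0.3), channels = c("cue", "reach"))
  ev <- list(cue = sort(runif(40, 1, 99)), reach = sort(runif(30, 1, 99)))
  X <- build_design(ev, 100, d)
  y <- as.numeric(X %*% rnorm(ncol(X))) + rnorm(nrow(X), 0, 0.5)
  fit <- fit_glm(X, y, glm_config(), design = d)
  # the selected candidate attains the sweep's maximum
  expect_equal(fit$r2_holdout, max(fit$sweep$r2_holdout))
  ols_row <- fit$sweep[fit$sweep$alpha == 0, ]
  expect_gte(fit$r2_holdout, ols_row$r2_holdout)
})

test_that("pure-noise responses give near-zero held-out R-squared", {
  set.seed(63)
  d <- event_design(lag_range = c(-0.5, 1), channels = c("cue", "reach"))
  ev <- list(cue = sort(runif(30, 2, 195)), reach = sort(runif(30, 2, 195)))
  X <- build_design(ev, 200, d)
  y <- rpois(nrow(X), 0.3)
  fit <- fit_glm(X, y, glm_config(), design = d)
  expect_lt(abs(fit$r2_holdout), 0.05)
})

test_that("POP kernels average the two failure types on the 0-5 s grid", {
  d <- event_design()
  co <- matrix(0, 9, 71, dimnames = list(glm_event_channels, NULL))
  co["failure_drop", ] <- 1
  co["failure_pellet_missing", ] <- 0
  co["success", ] <- 2
  k <- extract_pop_kernels(co, d)
  expect_equal(length(k$lag_s), 51)
  expect_equal(range(k$lag_s), c(0, 5))
  expect_true(all(k$kernels["failure", ] == 0.5))
  expect_true(all(k$kernels["success", ] == 2))
  expect_true(all(k$kernels["cued_failure", ] == 0))
  co2 <- co[setdiff(rownames(co), "success"), ]
  expect_error(extract_pop_kernels(co2, d), "missing outcome")
})

test_that("planted kernels are recovered from synthetic spike trains", {
  # balanced deterministic session, linear-link generator, OLS + ridge
  s <- make_balanced_session(100)            # 400 trials
  cfg_s <- spike_gen_config(n_units = 3, kernel_jitter_sd = 0,
                            group_fractions = c(group1 = 1, group2 = 0,
                                                other = 0))
  sp <- generate_population_spikes(s, cfg_s, seed = 64)
  X <- build_design(session_event_channels(s), sp$duration_s)
  cors <- c()
  for (u in 1:3) {
    fit <- suppressWarnings(
      fit_glm(X, bin_spikes(sp$units[[u]]$spike_times, sp$duration_s),
              glm_config(alpha_grid = c(0, 0.01), l1_ratio_grid = 0)))
    eff <- effective_event_kernels(fit)
    tpl <- sp$truth$units[[u]]$kernels
    truth_eff <- rbind(
      cued_success = tpl["reach", ] + tpl["success", ] + tpl["cued_success", ],
      uncued_success = tpl["reach", ] + tpl["success", ]
    )
    for (nm in rownames(truth_eff)) {
      cors <- c(cors, cor(eff[nm, ], truth_eff[nm, ]))
    }
  }
  expect_gt(mean(cors), 0.9)
  expect_true(all(cors > 0.85))
})

test_that("kernel recovery error shrinks with trial count", {
  errs <- vapply(c(12, 40, 120), function(n_per) {
    s <- make_balanced_session(n_per)
    cfg_s <- spike_gen_config(n_units = 1, kernel_jitter_sd = 0,
                              group_fractions = c(group1 = 1, group2 = 0,
                                                  other = 0))
    sp <- generate_population_spikes(s, cfg_s, seed = 65)
    X <- build_design(session_event_channels(s), sp$duration_s)
    fit <- suppressWarnings(
      fit_glm(X, bin_spikes(sp$units[[1]]$spike_times, sp$duration_s),
              glm_config(alpha_grid = 0)))
    eff <- effective_event_kernels(fit)
    tpl <- sp$truth$units[[1]]$kernels
    truth <- tpl["reach", ] + tpl["success", ] + tpl["cued_success", ]
    mean(abs(eff["cued_success", ] - truth))
  }, 0)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
})
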