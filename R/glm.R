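#' Behavioral event channels of the neural encoding model
#'
#' The nine behavioral events regressed against neural activity. Outcome
#' events are timestamped at the moment the arm is outstretched; the
#' `cued_*` channels duplicate outcome events for reaches that occurred
#' within 3 s of cue onset, so their coefficients capture the interaction
#' of outcome with sensory context.
#' @export
glm_event_channels <- c("cue", "distractor", "reach", "success",
                        "failure_drop", "failure_pellet_missing",
                        "cued_success", "cued_failure_drop",
                        "cued_failure_pellet_missing")

#' Event-design geometry
#'
#' @param bin_s time bin, seconds (default 0.1).
#' @param lag_range lag grid bounds `[min, max]` in seconds, inclusive;
#'   the default -2 to +5 s at 0.1-s steps gives 71 lags and, with nine
#'   event channels, 639 design columns.
#' @param channels event channel names.
#' @return list of class `"event_design"` with `bin_s`, `lags` (seconds),
#'   `channels`, `n_columns`.
#' @export
event_design <- function(bin_s = 0.1, lag_range = c(-2, 5),
                         channels = glm_event_channels) {
  stopifnot(bin_s > 0, lag_range[1] < lag_range[2])
  lags <- seq(round(lag_range[1] / bin_s), round(lag_range[2] / bin_s)) * bin_s
  structure(list(bin_s = bin_s, lags = lags, channels = channels,
                 n_columns = length(channels) * length(lags)),
            class = "event_design")
}

#' Extract the nine event-time channels from a session
#'
#' Outcome events are the reach times, split by outcome type; a reach is
#' "cued" when it falls within `cued_window_s` of its trial's cue onset.
#' The rare reaches that touched but failed to dislodge the pellet are
#' carried on the dropped-pellet channel (the pellet was present).
#'
#' @param session a [reach_session()].
#' @param cued_window_s seconds after cue onset within which an outcome
#'   counts as cued (default 3, the physiology convention).
#' @return named list of numeric time vectors, one per channel in
#'   [glm_event_channels].
#' @export
session_event_channels <- function(session, cued_window_s = 3) {
  trials <- session$trials
  cue <- session_cue_times(session)
  distractor <- sort(unlist(lapply(trials, `[[`, "distractor_times"),
                            use.names = FALSE))
  rows <- do.call(rbind, lapply(trials, function(tr) {
    if (!nrow(tr$reaches)) return(NULL)
    data.frame(t_arm = tr$reaches$t_arm, outcome = tr$reaches$outcome,
               t_cue = if (tr$cue_present) tr$t_cue else NA_real_)
  }))
  ev <- stats::setNames(vector("list", length(glm_event_channels)),
                        glm_event_channels)
  for (nm in names(ev)) ev[[nm]] <- numeric()
  ev$cue <- cue
  ev$distractor <- distractor
  if (!is.null(rows)) {
    rows <- rows[order(rows$t_arm), ]
    cued <- !is.na(rows$t_cue) &
      rows$t_arm >= rows$t_cue & rows$t_arm < rows$t_cue + cued_window_s
    drop_like <- rows$outcome %in% c("drop", "missed_pellet")
    pm <- rows$outcome == "pellet_missing"
    succ <- rows$outcome == "success"
    ev$reach <- rows$t_arm
    ev$success <- rows$t_arm[succ]
    ev$failure_drop <- rows$t_arm[drop_like]
    ev$failure_pellet_missing <- rows$t_arm[pm]
    ev$cued_success <- rows$t_arm[succ & cued]
    ev$cued_failure_drop <- rows$t_arm[drop_like & cued]
    ev$cued_failure_pellet_missing <- rows$t_arm[pm & cued]
  }
  ev
}

#' Build the time-shifted event indicator matrix
#'
#' Column (e, tau) carries a 1 in time bin t whenever event e occurred in
#' bin t - tau; bins where the shifted time falls outside the session are
#' left at 0. Columns are ordered event-major, lag-minor. The matrix is
#' sparse (class `dgCMatrix`).
#'
#' @param events named list of event-time vectors; names must match
#'   `design$channels`.
#' @param duration_s session duration, seconds.
#' @param design an [event_design()].
#' @return sparse indicator matrix, `ceiling(duration_s / bin)` rows by
#'   `design$n_columns` columns, with informative dimnames on columns.
#' @export
build_design <- function(events, duration_s, design = event_design()) {
  stopifnot(inherits(design, "event_design"))
  unknown <- setdiff(names(events), design$channels)
  if (length(unknown)) {
    stop("unknown event type(s): ", paste(unknown, collapse = ", "))
  }
  n_bins <- ceiling(duration_s / design$bin_s)
  n_lags <- length(design$lags)
  lag_bins <- round(design$lags / design$bin_s)
  ii <- integer(); jj <- integer()
  for (e in seq_along(design$channels)) {
    ch <- design$channels[e]
    tt <- events[[ch]]
    if (is.null(tt) || !length(tt)) next
    if (any(tt < 0 | tt > duration_s)) {
      stop("event times must lie within the session span")
    }
    b0 <- pmin(n_bins, 1L + floor(tt / design$bin_s))
    for (l in seq_len(n_lags)) {
      rows <- unique(b0 + lag_bins[l])
      rows <- rows[rows >= 1L & rows <= n_bins]
      if (length(rows)) {
        ii <- c(ii, rows)
        jj <- c(jj, rep((e - 1L) * n_lags + l, length(rows)))
      }
    }
  }
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(n_bins, design$n_columns))
  colnames(X) <- paste0(rep(design$channels, each = n_lags), "@",
                        sprintf("%+.1f", rep(design$lags, length(design$channels))))
  X
}

#' Bin spike counts on the design grid
#'
#' @param spike_times numeric vector, seconds.
#' @param duration_s session duration, seconds.
#' @param bin_s bin width, seconds.
#' @return integer vector of counts, `ceiling(duration_s / bin_s)` long.
#' @export
bin_spikes <- function(spike_times, duration_s, bin_s = 0.1) {
  n_bins <- ceiling(duration_s / bin_s)
  spike_times <- spike_times[spike_times >= 0 & spike_times < duration_s]
  idx <- pmin(n_bins, 1L + floor(spike_times / bin_s))
  tabulate(idx, nbins = n_bins)
}

#' GLM fitting configuration
#'
#' The regularization sweep covers ordinary least squares (alpha = 0) and
#' every combination of penalty strength alpha in \{0.01, 0.1, 1\} with
#' mixing l1_ratio in \{0, 0.1, 0.5, 0.9, 1\} (ridge through lasso). The
#' final `test_fraction` of time bins is held out; the sweep selects the
#' candidate with the highest held-out R-squared, breaking ties toward
#' larger alpha, then larger l1_ratio (sparser models).
#'
#' @param alpha_grid penalty strengths; must include 0 for the OLS
#'   baseline to be fitted.
#' @param l1_ratio_grid elastic-net mixing values in `[0, 1]`.
#' @param cv_folds number of contiguous time blocks used for the
#'   diagnostic cross-validated R-squared of the selected model.
#' @param test_fraction fraction of time bins held out (taken from the
#'   end of the session, so no future data leaks into training).
#' @param seed integer seed (recorded; the blocked folds are
#'   deterministic).
#' @return list of class `"glm_config"`.
#' @export
glm_config <- function(alpha_grid = c(0, 0.01, 0.1, 1),
                       l1_ratio_grid = c(0, 0.1, 0.5, 0.9, 1),
                       cv_folds = 5, test_fraction = 0.10, seed = 1L) {
  stopifnot(length(alpha_grid) >= 1, length(l1_ratio_grid) >= 1,
            all(l1_ratio_grid >= 0 & l1_ratio_grid <= 1),
            test_fraction > 0, test_fraction < 1, cv_folds >= 2)
  structure(list(alpha_grid = sort(unique(alpha_grid)),
                 l1_ratio_grid = sort(unique(l1_ratio_grid)),
                 cv_folds = cv_folds, test_fraction = test_fraction,
                 seed = seed), class = "glm_config")
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, with SS_res the sum of squared residuals
#' after subtracting the model fit and SS_tot the total sum of squares
#' about the mean of `y`.
#'
#' @param y observed values.
#' @param y_hat fitted values, same length.
#' @return numeric scalar (may be negative for bad fits).
#' @export
r_squared <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R-squared undefined for constant y")
  1 - sum((y - y_hat)^2) / ss_tot
}

# minimum-norm least squares with unpenalized intercept; X sparse or dense
.ols_fit <- function(X, y) {
  Xc <- cbind(1, X)
  XtX <- as.matrix(Matrix::crossprod(Xc))
  Xty <- as.numeric(Matrix::crossprod(Xc, y))
  beta <- tryCatch(solve(XtX, Xty), error = function(e) {
    # rank-deficient design (e.g. exactly collinear event channels):
    # return the minimum-norm solution
    MASS::ginv(XtX) %*% Xty
  })
  beta <- as.numeric(beta)
  list(intercept = beta[1], coef = beta[-1])
}

.predict_lin <- function(X, intercept, coef) {
  as.numeric(X %*% coef) + intercept
}

#' Fit the linear-link event-kernel GLM with a regularization sweep
#'
#' Regresses binned spike counts on the time-shifted event indicators
#' with an identity (linear) link. Candidates are ordinary least squares
#' plus the elastic-net grid of [glm_config()]; each is fitted on the
#' first `1 - test_fraction` of time bins and scored by R-squared on the
#' held-out tail, and the best-scoring model is returned. Indicator
#' regressors are not standardized and the intercept is unpenalized.
#'
#' @param X design matrix from [build_design()].
#' @param y spike counts per bin (see [bin_spikes()]).
#' @param cfg a [glm_config()].
#' @param design the [event_design()] describing the columns.
#' @return object of class `"glm_fit"`: list with `coefficients` (matrix
#'   channels x lags), `intercept`, `alpha`, `l1_ratio`, `r2_holdout`,
#'   `cv_r2` (blocked-CV diagnostic for the selected hyperparameters),
#'   `sweep` (data.frame of all candidates), `design`.
#' @export
fit_glm <- function(X, y, cfg = glm_config(), design = event_design()) {
  stopifnot(nrow(X) == length(y))
  if (any(Matrix::colSums(abs(X)) == 0)) {
    warning("design contains all-zero columns; their coefficients are 0 under penalty")
  }
  n <- nrow(X)
  n_test <- max(1L, round(cfg$test_fraction * n))
  idx_train <- seq_len(n - n_test)
  idx_test <- (n - n_test + 1L):n
  Xtr <- X[idx_train, , drop = FALSE]
  ytr <- y[idx_train]
  Xte <- X[idx_test, , drop = FALSE]
  yte <- y[idx_test]

  cand <- list()
  if (0 %in% cfg$alpha_grid) {
    f <- .ols_fit(Xtr, ytr)
    cand[[length(cand) + 1L]] <- list(alpha = 0, l1_ratio = NA_real_,
                                      intercept = f$intercept, coef = f$coef)
  }
  pos_alpha <- cfg$alpha_grid[cfg$alpha_grid > 0]
  if (length(pos_alpha)) {
    lam <- sort(pos_alpha, decreasing = TRUE)
    for (l1 in cfg$l1_ratio_grid) {
      # glmnet's (lambda, alpha) matches the (alpha, l1_ratio) sweep:
      # loss = RSS/(2n) + lambda * (alpha*|b|_1 + (1-alpha)/2*|b|_2^2)
      gfit <- glmnet::glmnet(Xtr, ytr, family = "gaussian",
                             alpha = max(l1, 1e-9), lambda = lam,
                             standardize = FALSE, intercept = TRUE)
      for (a in pos_alpha) {
        co <- as.numeric(stats::coef(gfit, s = a, exact = FALSE))
        cand[[length(cand) + 1L]] <- list(alpha = a, l1_ratio = l1,
                                          intercept = co[1], coef = co[-1])
      }
    }
  }
  scores <- vapply(cand, function(cc) {
    r_squared(yte, .predict_lin(Xte, cc$intercept, cc$coef))
  }, 0)
  sweep <- data.frame(alpha = vapply(cand, `[[`, 0, "alpha"),
                      l1_ratio = vapply(cand, `[[`, 0, "l1_ratio"),
                      r2_holdout = scores)
  # argmax with ties broken toward larger alpha, then larger l1_ratio
  ord <- order(-scores, -sweep$alpha, -ifelse(is.na(sweep$l1_ratio), -1,
                                              sweep$l1_ratio))
  best <- cand[[ord[1]]]

  # blocked-CV diagnostic for the selected hyperparameters
  fold_id <- cut(seq_along(idx_train), breaks = cfg$cv_folds, labels = FALSE)
  cv_r2 <- vapply(seq_len(cfg$cv_folds), function(k) {
    tr <- idx_train[fold_id != k]
    va <- idx_train[fold_id == k]
    f <- if (best$alpha == 0) {
      .ols_fit(X[tr, , drop = FALSE], y[tr])
    } else {
      g <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = "gaussian",
                          alpha = max(best$l1_ratio, 1e-9),
                          lambda = sort(unique(c(best$alpha, pos_alpha)),
                                        decreasing = TRUE),
                          standardize = FALSE, intercept = TRUE)
      co <- as.numeric(stats::coef(g, s = best$alpha, exact = FALSE))
      list(intercept = co[1], coef = co[-1])
    }
    r_squared(y[va], .predict_lin(X[va, , drop = FALSE], f$intercept, f$coef))
  }, 0)

  n_lags <- length(design$lags)
  coef_mat <- matrix(best$coef, nrow = length(design$channels),
                     ncol = n_lags, byrow = TRUE,
                     dimnames = list(design$channels, sprintf("%+.1f", design$lags)))
  structure(list(coefficients = coef_mat, intercept = best$intercept,
                 alpha = best$alpha, l1_ratio = best$l1_ratio,
                 r2_holdout = max(scores), cv_r2 = mean(cv_r2),
                 sweep = sweep, design = design),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf(
    "<glm_fit> alpha = %s, l1_ratio = %s | holdout R^2 = %.3f, CV R^2 = %.3f\n",
    format(x$alpha), format(x$l1_ratio), x$r2_holdout, x$cv_r2))
  invisible(x)
}

#' Extract the four post-outcome-period kernels
#'
#' Restricts the fitted coefficients to lags 0--5 s after the outstretched
#' arm and returns the success, failure, cued-success and cued-failure
#' kernels; each failure kernel is the average of its dropped-pellet and
#' pellet-missing coefficients.
#'
#' @param fit a [fit_glm()] result (or a coefficient matrix with the
#'   standard channel rows and lag columns named as in [fit_glm()]).
#' @param design the [event_design()]; defaults to the fit's design.
#' @return list of class `"pop_kernels"` with `lag_s` (0 to 5 s) and
#'   `kernels`, a 4 x n_lag matrix with rows `success`, `failure`,
#'   `cued_success`, `cued_failure`.
#' @export
extract_pop_kernels <- function(fit, design = NULL) {
  co <- if (inherits(fit, "glm_fit")) fit$coefficients else fit
  if (is.null(design)) {
    design <- if (inherits(fit, "glm_fit")) fit$design else event_design()
  }
  need <- c("success", "failure_drop", "failure_pellet_missing",
            "cued_success", "cued_failure_drop", "cued_failure_pellet_missing")
  if (!all(need %in% rownames(co))) stop("missing outcome event channel(s)")
  keep <- design$lags >= 0 & design$lags <= 5
  lag_s <- design$lags[keep]
  k <- rbind(
    success = co["success", keep],
    failure = (co["failure_drop", keep] +
                 co["failure_pellet_missing", keep]) / 2,
    cued_success = co["cued_success", keep],
    cued_failure = (co["cued_failure_drop", keep] +
                      co["cued_failure_pellet_missing", keep]) / 2
  )
  structure(list(lag_s = lag_s, kernels = k), class = "pop_kernels")
}

#' Identifiable per-event response kernels
#'
#' The reach channel fires on every outcome event, so the raw reach and
#' outcome coefficients are only identified in combination. This helper
#' returns the total modeled response to each concrete event type (the
#' sum of every channel triggered by that event), which is identifiable
#' regardless of how a penalty distributes weight across the overlapping
#' channels.
#'
#' @param fit a [fit_glm()] result.
#' @return matrix with rows `cue`, `distractor`, `uncued_success`,
#'   `uncued_drop`, `uncued_pellet_missing`, `cued_success`, `cued_drop`,
#'   `cued_pellet_missing` and one column per lag.
#' @export
effective_event_kernels <- function(fit) {
  co <- fit$coefficients
  rbind(
    cue = co["cue", ],
    distractor = co["distractor", ],
    uncued_success = co["reach", ] + co["success", ],
    uncued_drop = co["reach", ] + co["failure_drop", ],
    uncued_pellet_missing = co["reach", ] + co["failure_pellet_missing", ],
    cued_success = co["reach", ] + co["success", ] + co["cued_success", ],
    cued_drop = co["reach", ] + co["failure_drop", ] +
      co["cued_failure_drop", ],
    cued_pellet_missing = co["reach", ] + co["failure_pellet_missing", ] +
      co["cued_failure_pellet_missing", ]
  )
}
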