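#' Tensor-regression condition labels
#'
#' The four behavioral conditions of the population analyses: uncued
#' success, uncued failure, cued success, cued failure (in this fixed
#' slice order).
#' @export
tensor_conditions <- c("success", "failure", "cued_success", "cued_failure")

#' Per-trial binned responses of a population
#'
#' Bins every unit's spikes around each trial's outcome reach. This is
#' the shared substrate of [build_tensor()], [validate_shuffles()] and
#' the decoding module.
#'
#' @param units list of [unit_recording()] objects.
#' @param trials data.frame with columns `t_arm` (outcome reach time,
#'   seconds) and `condition` (one of [tensor_conditions]).
#' @param window numeric `[a, b]` around the reach, seconds.
#' @param bin_s bin width, seconds.
#' @return list of class `"trial_tensor"`: `responses` (array units x
#'   trials x bins, rates in Hz), `condition` (per trial), `lag_s` (bin
#'   centers), `unit_ids`.
#' @export
trial_tensor <- function(units, trials, window = c(0, 5), bin_s = 0.1) {
  stopifnot(all(c("t_arm", "condition") %in% names(trials)),
            all(trials$condition %in% tensor_conditions))
  edges <- seq(window[1], window[2], by = bin_s)
  nb <- length(edges) - 1L
  N <- length(units)
  M <- nrow(trials)
  arr <- array(0, dim = c(N, M, nb))
  for (u in seq_len(N)) {
    sp <- if (inherits(units[[u]], "unit_recording")) {
      units[[u]]$spike_times
    } else {
      units[[u]]
    }
    for (m in seq_len(M)) {
      rel <- sp - trials$t_arm[m]
      rel <- rel[rel >= window[1] & rel < window[2]]
      if (length(rel)) {
        idx <- pmin(nb, 1L + floor((rel - window[1]) / bin_s))
        arr[u, m, ] <- tabulate(idx, nbins = nb) / bin_s
      }
    }
  }
  ids <- vapply(seq_len(N), function(u) {
    if (inherits(units[[u]], "unit_recording")) units[[u]]$unit_id
    else sprintf("u%03d", u)
  }, "")
  structure(list(responses = arr, condition = trials$condition,
                 lag_s = edges[-(nb + 1L)] + bin_s / 2, unit_ids = ids),
            class = "trial_tensor")
}

# average a trial_tensor into condition slices and apply the failure
# alignment shift: failure responses are advanced by `shift_bins` so the
# post-failure dopamine dip (~1.6 s) lines up with the post-success peak
# (~0.83 s); unmatched edge bins are dropped from all conditions.
.condition_slices <- function(tt, trial_idx_by_cond, shift_bins) {
  nb <- dim(tt$responses)[3]
  keep_succ <- seq_len(nb - shift_bins)
  keep_fail <- keep_succ + shift_bins
  lapply(stats::setNames(tensor_conditions, tensor_conditions), function(cond) {
    idx <- trial_idx_by_cond[[cond]]
    if (!length(idx)) stop(sprintf("condition '%s' has no trials", cond))
    sl <- apply(tt$responses[, idx, , drop = FALSE], c(1, 3), mean)
    if (grepl("failure", cond)) sl[, keep_fail, drop = FALSE]
    else sl[, keep_succ, drop = FALSE]
  })
}

#' Build the neurons x time x conditions tensor
#'
#' Trial-averages each unit's binned response within each of the four
#' behavioral conditions and time-shifts the failure slices by
#' `round(failure_shift_s / bin_s)` bins (default 0.77 s, i.e. 8 bins on
#' the 0.1-s grid) so the characteristic post-failure dip aligns with the
#' post-success peak; edge bins without a partner are dropped from every
#' condition so all slices share the same time axis.
#'
#' @param tt a [trial_tensor()] built from training-set trials only.
#' @param failure_shift_s failure-alignment shift, seconds.
#' @return list of class `"condition_tensor"`: `data` (array N x T x 4),
#'   `conditions`, `lag_s` (success-slice time axis), `shift_bins`,
#'   `unit_ids`.
#' @export
build_tensor <- function(tt, failure_shift_s = 0.77) {
  stopifnot(inherits(tt, "trial_tensor"))
  bin_s <- diff(tt$lag_s[1:2])
  shift_bins <- round(failure_shift_s / bin_s)
  idx_by_cond <- lapply(stats::setNames(tensor_conditions, tensor_conditions),
                        function(cc) which(tt$condition == cc))
  slices <- .condition_slices(tt, idx_by_cond, shift_bins)
  arr <- array(0, dim = c(dim(slices[[1]]), 4))
  for (k in seq_len(4)) arr[, , k] <- slices[[k]]
  structure(list(data = arr, conditions = tensor_conditions,
                 lag_s = tt$lag_s[seq_len(dim(arr)[2])],
                 shift_bins = shift_bins, unit_ids = tt$unit_ids),
            class = "condition_tensor")
}


# scores S[m, r] = a_r' X_m b_r for every slice m (handles R = 1)
.factor_scores <- function(XB, A, R) {
  S <- vapply(XB, function(xb) colSums(A * xb), numeric(R))
  if (is.matrix(S)) t(S) else matrix(S, ncol = 1)
}
#' Optimizer configuration for the Kruskal-tensor regression
#'
#' @param lr ADAM learning rate (default 0.007).
#' @param init_scale factors initialized uniformly on `[0, init_scale]`
#'   (default 0.625).
#' @param l2 ridge penalty on all factor entries (default 1e-3).
#' @param max_epochs optimization cap.
#' @param tol relative-loss-change convergence tolerance, evaluated every
#'   `tol_epochs` epochs.
#' @param tol_epochs epochs between convergence checks.
#' @param scale_input divide the tensor by its maximum absolute entry
#'   before optimization (a conditioning choice; the stored scale is
#'   reapplied at prediction time).
#' @return list of class `"kruskal_config"`.
#' @export
kruskal_config <- function(lr = 0.007, init_scale = 0.625, l2 = 1e-3,
                           max_epochs = 20000, tol = 1e-6, tol_epochs = 50,
                           scale_input = TRUE) {
  stopifnot(lr > 0, init_scale > 0, l2 >= 0, max_epochs >= 1, tol > 0)
  structure(as.list(environment()), class = "kruskal_config")
}

#' Fit the rank-R Kruskal-tensor multinomial regression
#'
#' Predicts the behavioral condition of each tensor slice from the
#' population activity. The regression weight tensor is constrained to a
#' rank-R Kruskal form, `B = sum_r a_r (x) b_r (x) c_r`, with neuron
#' factors `a_r` kept entrywise non-negative (projection to 0 after each
#' step); the class logits of slice m are the inner products
#' `<X[,,m], B[,,k]>`. The cross-entropy loss plus an L2 penalty is
#' minimized with ADAM until the relative loss change falls below the
#' tolerance or the epoch cap is reached.
#'
#' @param tensor a [build_tensor()] result (or a bare N x T x C array).
#' @param R rank (number of components).
#' @param cfg a [kruskal_config()].
#' @param seed integer seed for the uniform initialization.
#' @return object of class `"kruskal_model"`: `A` (N x R, >= 0), `B`
#'   (T x R), `C` (C x R), `loss` (final), `loss_trace` (every
#'   `tol_epochs` epochs), `epochs`, `converged`, `config`, `seed`,
#'   `input_scale`.
#' @export
fit_kruskal_mnlr <- function(tensor, R = 2, cfg = kruskal_config(),
                             seed = 1L) {
  X <- if (inherits(tensor, "condition_tensor")) tensor$data else tensor
  stopifnot(length(dim(X)) == 3, R >= 1)
  dn <- dim(X)
  N <- dn[1]; Tt <- dn[2]; C <- dn[3]
  scale <- if (cfg$scale_input) max(abs(X), 1e-12) else 1
  Xs <- lapply(seq_len(C), function(m) X[, , m] / scale)
  y <- seq_len(C)  # slice m belongs to class m

  set.seed(seed)
  A <- matrix(stats::runif(N * R, 0, cfg$init_scale), N, R)
  B <- matrix(stats::runif(Tt * R, 0, cfg$init_scale), Tt, R)
  Cf <- matrix(stats::runif(C * R, 0, cfg$init_scale), C, R)

  adam <- function() list(m = 0, v = 0)
  st <- list(A = adam(), B = adam(), C = adam())
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- function(state, par, grad, t) {
    state$m <- b1 * state$m + (1 - b1) * grad
    state$v <- b2 * state$v + (1 - b2) * grad^2
    mh <- state$m / (1 - b1^t)
    vh <- state$v / (1 - b2^t)
    list(state = state, par = par - cfg$lr * mh / (sqrt(vh) + eps))
  }

  ce_of <- function(S) {
    Z <- S %*% t(Cf)                      # C samples x C classes
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    -mean(log(pmax(P[cbind(seq_len(C), y)], 1e-300)))
  }
  loss_of <- function(S) {
    ce_of(S) + cfg$l2 * (sum(A^2) + sum(B^2) + sum(Cf^2))
  }

  loss_trace <- numeric()
  prev_loss <- Inf
  converged <- FALSE
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    # S[m, r] = a_r' X_m b_r
    XB <- lapply(Xs, function(Xm) Xm %*% B)          # N x R each
    S <- .factor_scores(XB, A, R)
    Z <- S %*% t(Cf)
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    if (any(!is.finite(P))) stop("tensor regression diverged (non-finite loss); config: lr=",
                                 cfg$lr, " l2=", cfg$l2, " R=", R)
    G <- P
    G[cbind(seq_len(C), y)] <- G[cbind(seq_len(C), y)] - 1
    G <- G / C                                       # dLoss/dZ
    gC <- t(G) %*% S + 2 * cfg$l2 * Cf
    H <- G %*% Cf                                    # dLoss/dS, C x R
    gA <- matrix(0, N, R); gB <- matrix(0, Tt, R)
    for (m in seq_len(C)) {
      gA <- gA + XB[[m]] * rep(H[m, ], each = N)
      gB <- gB + crossprod(Xs[[m]], A) * rep(H[m, ], each = Tt)
    }
    gA <- gA + 2 * cfg$l2 * A
    gB <- gB + 2 * cfg$l2 * B

    up <- step(st$A, A, gA, epoch); st$A <- up$state; A <- pmax(up$par, 0)
    up <- step(st$B, B, gB, epoch); st$B <- up$state; B <- up$par
    up <- step(st$C, Cf, gC, epoch); st$C <- up$state; Cf <- up$par

    if (epoch %% cfg$tol_epochs == 0L) {
      # convergence is judged on the cross-entropy term: the quantity the
      # optimization minimizes until convergence (the penalty keeps
      # drifting long after the fit has stabilized)
      cur <- ce_of(S)
      loss_trace <- c(loss_trace, loss_of(S))
      if (is.finite(prev_loss) &&
          abs(prev_loss - cur) < cfg$tol * max(abs(prev_loss), 1e-12)) {
        converged <- TRUE
        break
      }
      prev_loss <- cur
    }
  }
  XB <- lapply(Xs, function(Xm) Xm %*% B)
  S <- .factor_scores(XB, A, R)
  structure(list(A = A, B = B, C = Cf, rank = R, loss = loss_of(S),
                 loss_trace = loss_trace, epochs = epoch,
                 converged = converged, config = cfg, seed = seed,
                 input_scale = scale),
            class = "kruskal_model")
}

#' @export
print.kruskal_model <- function(x, ...) {
  cat(sprintf("<kruskal_model> rank %d | loss %.5f after %d epochs%s\n",
              x$rank, x$loss, x$epochs,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Class probabilities for condition slices under a fitted model
#'
#' @param model a [fit_kruskal_mnlr()] result.
#' @param slices list of N x T activity matrices (or an N x T x M array).
#' @return matrix M x C of predicted condition probabilities.
#' @export
predict_kruskal <- function(model, slices) {
  if (is.array(slices) && length(dim(slices)) == 3) {
    slices <- lapply(seq_len(dim(slices)[3]), function(m) slices[, , m])
  }
  XB <- lapply(slices, function(Xm) (Xm / model$input_scale) %*% model$B)
  S <- .factor_scores(XB, model$A, model$rank)
  Z <- S %*% t(model$C)
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z) / rowSums(exp(Z))
  colnames(P) <- tensor_conditions[seq_len(ncol(P))]
  P
}

#' Joint loading penalty of the neuron factors
#'
#' `J = sum_n sum_{i != j} |w_ni + w_nj| / sum_n sum_{i != j} |w_ni - w_nj|`
#' over all factor pairs. With non-negative loadings, J is small when
#' different factors load on disjoint neuron groups and grows as factors
#' share neurons; identical factors give a zero denominator, reported as
#' `Inf`.
#'
#' @param A neuron-factor matrix (N x R, entries >= 0) or a
#'   `kruskal_model`.
#' @return numeric scalar (>= 0, possibly `Inf`).
#' @export
joint_loading_penalty <- function(A) {
  if (inherits(A, "kruskal_model")) A <- A$A
  stopifnot(is.matrix(A), ncol(A) >= 2)
  num <- 0; den <- 0
  R <- ncol(A)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      num <- num + sum(abs(A[, i] + A[, j]))
      den <- den + sum(abs(A[, i] - A[, j]))
    }
  }
  if (den == 0) Inf else num / den
}

#' Component weights of a fitted model
#'
#' Per component, the sum of absolute values of its mean-subtracted
#' factor entries (each factor mean-subtracted separately); comparable
#' weights indicate the solution uses its components evenly.
#'
#' @param model a [fit_kruskal_mnlr()] result.
#' @return numeric vector, one weight per component.
#' @export
component_weights <- function(model) {
  vapply(seq_len(model$rank), function(r) {
    sum(abs(model$A[, r] - mean(model$A[, r]))) +
      sum(abs(model$B[, r] - mean(model$B[, r]))) +
      sum(abs(model$C[, r] - mean(model$C[, r])))
  }, 0)
}

#' Rank sweep and solution selection for the tensor regression
#'
#' Re-runs the optimization `runs_per_rank` times for every rank in
#' `ranks`, reports the loss of every run (the rank choice is a judgment
#' made on this loss table; rank 2 is the default), and among the runs of
#' the chosen rank returns the solution minimizing the joint loading
#' penalty J.
#'
#' @param tensor a [build_tensor()] result.
#' @param ranks ranks to sweep (default 1:5).
#' @param runs_per_rank restarts per rank (default 10).
#' @param chosen_rank rank of the returned solution (default 2).
#' @param cfg a [kruskal_config()].
#' @param seed integer seed; run seeds are derived deterministically.
#' @return list with `model` (the chosen run), `rank`, `diagnostics`
#'   (data.frame rank / run / loss / J / converged), and
#'   `component_weights` of the chosen model.
#' @export
select_model <- function(tensor, ranks = 1:5, runs_per_rank = 10,
                         chosen_rank = 2, cfg = kruskal_config(),
                         seed = 1L) {
  stopifnot(chosen_rank %in% ranks)
  runs <- list()
  diag_rows <- list()
  for (R in ranks) {
    for (run in seq_len(runs_per_rank)) {
      run_seed <- (seed * 1000L + R * 100L + run) %% .Machine$integer.max
      fit <- fit_kruskal_mnlr(tensor, R = R, cfg = cfg, seed = run_seed)
      J <- if (R >= 2) joint_loading_penalty(fit$A) else NA_real_
      key <- sprintf("r%d_run%d", R, run)
      runs[[key]] <- fit
      diag_rows[[key]] <- data.frame(rank = R, run = run, loss = fit$loss,
                                     J = J, converged = fit$converged)
    }
  }
  diagnostics <- do.call(rbind, c(diag_rows, list(make.row.names = FALSE)))
  sub <- diagnostics[diagnostics$rank == chosen_rank, ]
  pick <- sub$run[which.min(if (chosen_rank >= 2) sub$J else sub$loss)]
  model <- runs[[sprintf("r%d_run%d", chosen_rank, pick)]]
  list(model = model, rank = chosen_rank, diagnostics = diagnostics,
       component_weights = component_weights(model))
}

#' Shuffle validation of the tensor regression on test data
#'
#' Predicts success versus failure on test-set activity and compares the
#' real prediction with predictions after shuffling neuron identity, the
#' time axis, or both. Each repetition draws a bootstrap resample of test
#' trials within every condition, averages them into condition slices
#' (with the same failure alignment used in training), and scores the
#' model's predicted class collapsed to success/failure.
#'
#' @param model a fitted `kruskal_model` (trained on the training split).
#' @param tt_test a [trial_tensor()] built from test-set trials.
#' @param n_rep bootstrap repetitions (each contributes 4 predictions).
#' @param failure_shift_s failure-alignment shift, seconds.
#' @param seed integer seed.
#' @return named numeric vector of accuracies: `real`,
#'   `shuffle_neurons`, `shuffle_time`, `shuffle_both`.
#' @export
validate_shuffles <- function(model, tt_test, n_rep = 50,
                              failure_shift_s = 0.77, seed = 1L) {
  stopifnot(inherits(tt_test, "trial_tensor"))
  bin_s <- diff(tt_test$lag_s[1:2])
  shift_bins <- round(failure_shift_s / bin_s)
  set.seed(seed)
  succ_classes <- c("success", "cued_success")
  modes <- c("real", "shuffle_neurons", "shuffle_time", "shuffle_both")
  hits <- stats::setNames(numeric(4), modes)
  total <- 0L
  N <- dim(tt_test$responses)[1]
  for (rep in seq_len(n_rep)) {
    idx_by_cond <- lapply(stats::setNames(tensor_conditions, tensor_conditions),
                          function(cc) {
                            ii <- which(tt_test$condition == cc)
                            sample(ii, length(ii), replace = TRUE)
                          })
    slices <- .condition_slices(tt_test, idx_by_cond, shift_bins)
    Tt <- ncol(slices[[1]])
    perm_n <- sample.int(N)
    perm_t <- sample.int(Tt)
    for (mode in modes) {
      sl <- lapply(slices, function(s) {
        if (mode %in% c("shuffle_neurons", "shuffle_both")) s <- s[perm_n, , drop = FALSE]
        if (mode %in% c("shuffle_time", "shuffle_both")) s <- s[, perm_t, drop = FALSE]
        s
      })
      P <- predict_kruskal(model, sl)
      pred <- tensor_conditions[max.col(P)]
      hit <- (pred %in% succ_classes) == (tensor_conditions %in% succ_classes)
      hits[mode] <- hits[mode] + sum(hit)
    }
    total <- total + 4L
  }
  hits / total
}
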