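#' Per-unit firing rates in the decoding window
#'
#' Mean firing rate of each unit in the window 1--5 s after the
#' outstretched arm (the first second is excluded so the cue offset
#' precedes the analysed window), per behavioral condition. Group labels
#' must come from the training split; the trials here are the test split.
#'
#' @param units list of [unit_recording()] objects.
#' @param trials data.frame with `t_arm` and `condition` (test trials).
#' @param window seconds after the reach, default `c(1, 5)`.
#' @return list of class `"pop_rates"`: `mean_rates` (matrix units x
#'   conditions, Hz), `trial_rates` (list per condition of units x trial
#'   matrices), `conditions`, `unit_ids`.
#' @export
pop_rates <- function(units, trials, window = c(1, 5)) {
  stopifnot(all(c("t_arm", "condition") %in% names(trials)),
            length(window) == 2L, window[1] < window[2])
  conds <- intersect(tensor_conditions, unique(trials$condition))
  missing <- setdiff(tensor_conditions, conds)
  if (length(missing)) {
    warning("condition(s) with no test trials excluded: ",
            paste(missing, collapse = ", "))
  }
  dur <- diff(window)
  N <- length(units)
  rate_one <- function(sp, t0) {
    sum(sp >= t0 + window[1] & sp < t0 + window[2]) / dur
  }
  trial_rates <- lapply(stats::setNames(conds, conds), function(cc) {
    ta <- trials$t_arm[trials$condition == cc]
    mat <- vapply(ta, function(t0) {
      vapply(units, function(u) {
        sp <- if (inherits(u, "unit_recording")) u$spike_times else u
        rate_one(sp, t0)
      }, 0)
    }, numeric(N))
    matrix(mat, nrow = N)
  })
  mean_rates <- vapply(trial_rates, rowMeans, numeric(N))
  if (!is.matrix(mean_rates)) {
    mean_rates <- matrix(mean_rates, nrow = N,
                         dimnames = list(NULL, names(trial_rates)))
  }
  ids <- vapply(seq_len(N), function(u) {
    if (inherits(units[[u]], "unit_recording")) units[[u]]$unit_id
    else sprintf("u%03d", u)
  }, "")
  rownames(mean_rates) <- ids
  structure(list(mean_rates = mean_rates, trial_rates = trial_rates,
                 conditions = conds, unit_ids = ids),
            class = "pop_rates")
}

#' Bootstrap scatter of group-1 versus group-2 population rates
#'
#' At each bootstrap iteration, `n` units are resampled with replacement
#' from each group and their rates averaged within group, yielding one
#' (group-2 mean, group-1 mean) point per behavioral condition. In
#' `single_trial` mode one random trial is drawn from each sampled unit
#' for each condition before averaging.
#'
#' @param rates a [pop_rates()] result (test-split rates).
#' @param groups integer vector (1/2; NA allowed) of group labels in
#'   `rates$unit_ids` order, frozen from the training split.
#' @param n units resampled per group (replacement, so `n` may exceed
#'   the group size).
#' @param n_boot bootstrap iterations (default 100).
#' @param mode `"trial_averaged"` or `"single_trial"`.
#' @param seed integer seed.
#' @return data.frame with columns `iter`, `condition`, `g1_rate`,
#'   `g2_rate` (`n_boot * n_conditions` rows).
#' @export
bootstrap_scatter <- function(rates, groups, n = 20, n_boot = 100,
                              mode = c("trial_averaged", "single_trial"),
                              seed = 1L) {
  stopifnot(inherits(rates, "pop_rates"),
            length(groups) == length(rates$unit_ids))
  mode <- match.arg(mode)
  g1 <- which(groups == 1)
  g2 <- which(groups == 2)
  if (!length(g1) || !length(g2)) stop("both groups must be non-empty")
  set.seed(seed)
  conds <- rates$conditions
  out <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    i1 <- sample(g1, n, replace = TRUE)
    i2 <- sample(g2, n, replace = TRUE)
    vals <- vapply(conds, function(cc) {
      if (mode == "trial_averaged") {
        c(mean(rates$mean_rates[i1, cc]), mean(rates$mean_rates[i2, cc]))
      } else {
        tm <- rates$trial_rates[[cc]]
        pick <- function(i) tm[i, sample.int(ncol(tm), 1L)]
        c(mean(vapply(i1, pick, 0)), mean(vapply(i2, pick, 0)))
      }
    }, c(g1 = 0, g2 = 0))
    out[[b]] <- data.frame(iter = b, condition = conds,
                           g1_rate = vals["g1", ], g2_rate = vals["g2", ],
                           row.names = NULL)
  }
  do.call(rbind, out)
}

# three-way class of a condition: cued success / uncued success /
# failure (cued and uncued failures combined)
.lda_class <- function(condition) {
  ifelse(condition == "cued_success", "cued_success",
         ifelse(condition == "success", "uncued_success", "failure"))
}

#' Three-way linear-discriminant accuracy of the rate scatter
#'
#' Fits a linear discriminant (equal priors, pooled covariance) to the
#' 2-D bootstrap points labeled cued success / uncued success / failure
#' (cued and uncued failures combined) and reports the resubstitution
#' accuracy, mirroring how separation quality is quantified in the
#' population analyses.
#'
#' @param points data.frame from [bootstrap_scatter()].
#' @return accuracy in `[0, 1]`.
#' @export
lda_accuracy <- function(points) {
  stopifnot(all(c("condition", "g1_rate", "g2_rate") %in% names(points)))
  cls <- .lda_class(points$condition)
  if (length(unique(cls)) < 2L) stop("need at least two classes")
  X <- cbind(points$g2_rate, points$g1_rate)
  classes <- sort(unique(cls))
  mus <- lapply(classes, function(k) colMeans(X[cls == k, , drop = FALSE]))
  pooled <- Reduce(`+`, lapply(classes, function(k) {
    Xi <- X[cls == k, , drop = FALSE]
    crossprod(scale(Xi, center = TRUE, scale = FALSE))
  })) / max(1, nrow(X) - length(classes))
  if (abs(det(pooled)) < 1e-12) {
    warning("near-singular within-class covariance; regularizing")
    pooled <- pooled + diag(max(diag(pooled), 1) * 1e-6, 2)
  }
  Sinv <- solve(pooled)
  # equal priors: assign to the class with maximal discriminant score
  scores <- vapply(seq_along(classes), function(k) {
    mu <- mus[[k]]
    as.numeric(X %*% (Sinv %*% mu)) - 0.5 * sum(mu * (Sinv %*% mu))
  }, numeric(nrow(X)))
  pred <- classes[max.col(scores)]
  mean(pred == cls)
}

#' Shuffle controls for the population decoding
#'
#' Re-runs the scatter-plus-LDA pipeline after destroying either the
#' group structure (`shuffle_group_identity`: unit group labels permuted)
#' or the condition structure (`shuffle_condition_labels`: each unit's
#' condition-wise rates permuted across conditions, preserving its
#' marginal rate distribution).
#'
#' @param rates a [pop_rates()] result.
#' @param groups group labels as in [bootstrap_scatter()].
#' @param mode which shuffle to apply.
#' @param n,n_boot,scatter_mode,seed passed to [bootstrap_scatter()];
#'   `seed` also drives the permutation.
#' @return accuracy under the shuffle.
#' @export
shuffle_controls <- function(rates, groups,
                             mode = c("shuffle_group_identity",
                                      "shuffle_condition_labels"),
                             n = 20, n_boot = 100,
                             scatter_mode = "trial_averaged", seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed + 7L)
  if (mode == "shuffle_group_identity") {
    lab <- which(groups %in% c(1L, 2L))
    groups[lab] <- sample(groups[lab])
    sh_rates <- rates
  } else {
    sh_rates <- rates
    nc <- length(rates$conditions)
    for (u in seq_len(nrow(rates$mean_rates))) {
      perm <- sample.int(nc)
      sh_rates$mean_rates[u, ] <- rates$mean_rates[u, perm]
    }
    # keep single-trial rates consistent with the permuted condition map
    for (cc in seq_along(rates$conditions)) {
      sh_rates$trial_rates[[cc]] <- rates$trial_rates[[cc]]
    }
  }
  pts <- bootstrap_scatter(sh_rates, groups, n = n, n_boot = n_boot,
                           mode = scatter_mode, seed = seed)
  lda_accuracy(pts)
}
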