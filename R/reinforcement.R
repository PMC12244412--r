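#' Trial classes usable as triplet conditions
#' @export
trial_classes <- c("cued_success", "cued_failure",
                   "uncued_success", "uncued_failure")

# per-trial behavior 2-vector: (cued-window rate, uncued-window rate), Hz
.trial_behavior <- function(trials, spec, reach_times = NULL) {
  if (is.null(reach_times)) {
    reach_times <- sort(unlist(lapply(trials, function(tr) tr$reaches$t_arm),
                               use.names = FALSE))
  }
  cued <- .window_counts(trials, spec$cued_window, reach_times) /
    diff(spec$cued_window)
  uncued <- .window_counts(trials, spec$uncued_window, reach_times) /
    diff(spec$uncued_window)
  cbind(cued = cued, uncued = uncued)
}

#' Extract three-trial sequences conditioned on the middle trial
#'
#' Collects all consecutive trial triplets (n-1, n, n+1) in which trial n
#' matches `condition`. With an inhibition filter, trial n is additionally
#' required to be interleaved with the opposite inhibition state:
#' `"control_interleaved"` keeps inhibition-off n trials followed by an
#' inhibition trial at position n+2, n+3, n+4 or n+5, and
#' `"inhibition_on"` keeps inhibition n trials followed by an
#' inhibition-off trial at one of those positions.
#'
#' @param trials a [reach_session()] or ordered list of [trial()] objects.
#' @param condition one of [trial_classes], `"any"` (every interior
#'   trial), or `"any_reach"` (interior trials with at least one reach).
#' @param inhibition_filter `"none"`, `"control_interleaved"` or
#'   `"inhibition_on"`.
#' @param spec a [window_spec()].
#' @param classes optional pre-computed vector from [classify_session()].
#' @return object of class `"triplet_set"`: list with `triplets` (a
#'   data.frame of 1-based indices `n_minus`, `n`, `n_plus`), `condition`,
#'   `inhibition_filter`, `behavior` (per-trial 2-column rate matrix) and
#'   `n_trials`.
#' @export
extract_triplets <- function(trials, condition = "cued_success",
                             inhibition_filter = c("none",
                                                   "control_interleaved",
                                                   "inhibition_on"),
                             spec = window_spec(), classes = NULL) {
  if (inherits(trials, "reach_session")) trials <- trials$trials
  inhibition_filter <- match.arg(inhibition_filter)
  stopifnot(condition %in% c(trial_classes, "any", "any_reach"))
  n <- length(trials)
  if (is.null(classes)) classes <- classify_session(trials, spec)
  has_inh <- vapply(trials, function(tr) !is.null(tr$inhibition_window), TRUE)
  has_reach <- vapply(trials, function(tr) nrow(tr$reaches) > 0, TRUE)

  idx <- seq_len(n)
  ok <- idx > 1L & idx < n
  ok <- ok & switch(condition,
                    any = TRUE,
                    any_reach = has_reach,
                    classes == condition)
  if (inhibition_filter != "none") {
    want_n <- inhibition_filter == "inhibition_on"
    inter <- vapply(idx, function(i) {
      ahead <- (i + 2L):(i + 5L)
      ahead <- ahead[ahead <= n]
      length(ahead) > 0 && any(has_inh[ahead] != want_n)
    }, TRUE)
    ok <- ok & (has_inh == want_n) & inter
  }
  sel <- idx[ok]
  structure(list(
    triplets = data.frame(n_minus = sel - 1L, n = sel, n_plus = sel + 1L),
    condition = condition,
    inhibition_filter = inhibition_filter,
    behavior = .trial_behavior(trials, spec),
    classes = classes,
    n_trials = n
  ), class = "triplet_set")
}

#' @export
print.triplet_set <- function(x, ...) {
  cat(sprintf("<triplet_set> %d triplets | condition = %s, filter = %s\n",
              nrow(x$triplets), x$condition, x$inhibition_filter))
  invisible(x)
}

#' Bootstrap the trial-to-trial behavioral shift
#'
#' The change in the two-dimensional behavior (cued-window reach rate,
#' uncued-window reach rate) from trial n-1 to trial n+1, conditioned on
#' the class of trial n. The point estimate is the difference of plain
#' means over all triplets (no resampling). Each bootstrap iteration
#' resamples the m triplets with replacement and records
#' `mean(behavior at n+1) - mean(behavior at n-1)`.
#'
#' @param tset a [extract_triplets()] result.
#' @param n_boot bootstrap iterations (100 for scatter clouds, 1000 for
#'   the smoothed histogram).
#' @param seed integer seed for the resampling.
#' @return object of class `"shift_estimate"`: list with `delta_cued`,
#'   `delta_uncued` (Hz, point estimates), `draws` (data.frame `iter`,
#'   `d_cued`, `d_uncued`), `se` (named pair), `n_triplets`.
#' @export
conditioned_shift <- function(tset, n_boot = 100, seed = 1L) {
  stopifnot(inherits(tset, "triplet_set"))
  m <- nrow(tset$triplets)
  if (!m) stop("empty triplet set")
  B <- tset$behavior
  pre <- B[tset$triplets$n_minus, , drop = FALSE]
  post <- B[tset$triplets$n_plus, , drop = FALSE]
  point <- colMeans(post) - colMeans(pre)
  set.seed(seed)
  draws <- t(vapply(seq_len(n_boot), function(i) {
    j <- sample.int(m, m, replace = TRUE)
    colMeans(post[j, , drop = FALSE]) - colMeans(pre[j, , drop = FALSE])
  }, c(cued = 0, uncued = 0)))
  structure(list(delta_cued = unname(point["cued"]),
                 delta_uncued = unname(point["uncued"]),
                 draws = data.frame(iter = seq_len(n_boot),
                                    d_cued = draws[, "cued"],
                                    d_uncued = draws[, "uncued"]),
                 se = c(cued = stats::sd(draws[, "cued"]),
                        uncued = stats::sd(draws[, "uncued"])),
                 n_triplets = m),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf(
    "<shift_estimate> d(cued) = %.4f +/- %.4f Hz, d(uncued) = %.4f +/- %.4f Hz (m = %d)\n",
    x$delta_cued, x$se["cued"], x$delta_uncued, x$se["uncued"], x$n_triplets))
  invisible(x)
}

#' Smoothed 2-D histogram of bootstrap shift draws
#'
#' Bins the bootstrap draws of (delta uncued, delta cued) on a regular
#' grid and smooths with an axis-aligned Gaussian (SD 0.0096 Hz along the
#' uncued axis and 0.024 Hz along the cued axis, as used for the shaded
#' density displays). The returned density integrates to 1.
#'
#' @param tset a [extract_triplets()] result.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed seed for the bootstrap.
#' @param sigma_x,sigma_y Gaussian smoothing SDs along the uncued (x) and
#'   cued (y) axes, Hz.
#' @param n_grid grid points per axis.
#' @param expand fractional range expansion beyond the data range.
#' @return list with `x` (uncued grid), `y` (cued grid), `density`
#'   (matrix `length(x)` x `length(y)`), and the underlying `shift`.
#' @export
shift_histogram <- function(tset, n_boot = 1000, seed = 1L,
                            sigma_x = 0.0096, sigma_y = 0.024,
                            n_grid = 101, expand = 0.10) {
  shift <- conditioned_shift(tset, n_boot = n_boot, seed = seed)
  xs <- shift$draws$d_uncued
  ys <- shift$draws$d_cued
  pad_rng <- function(v, sig) {
    r <- range(v)
    if (diff(r) == 0) r <- r + c(-1, 1) * max(sig, 1e-6)
    r + c(-1, 1) * (expand * diff(r) + 3 * sig)
  }
  gx <- seq(pad_rng(xs, sigma_x)[1], pad_rng(xs, sigma_x)[2], length.out = n_grid)
  gy <- seq(pad_rng(ys, sigma_y)[1], pad_rng(ys, sigma_y)[2], length.out = n_grid)
  dx <- diff(gx[1:2]); dy <- diff(gy[1:2])
  ix <- findInterval(xs, gx - dx / 2, all.inside = TRUE)
  iy <- findInterval(ys, gy - dy / 2, all.inside = TRUE)
  h <- matrix(0, n_grid, n_grid)
  for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
  smooth_1d <- function(mat, sigma, step, along_rows) {
    half <- max(1L, ceiling(4 * sigma / step))
    kern <- stats::dnorm(seq(-half, half) * step, sd = sigma)
    kern <- kern / sum(kern)
    apply_fun <- function(v) {
      stats::convolve(v, rev(kern), type = "open")[(half + 1):(half + length(v))]
    }
    if (along_rows) apply(mat, 2, apply_fun) else t(apply(mat, 1, apply_fun))
  }
  h <- smooth_1d(h, sigma_x, dx, along_rows = TRUE)
  h <- smooth_1d(h, sigma_y, dy, along_rows = FALSE)
  h <- h / (sum(h) * dx * dy)
  list(x = gx, y = gy, density = h, shift = shift)
}

#' Backwards-time control for the conditioned shift
#'
#' Re-runs the triplet analysis with the conditioning moved one trial into
#' the future: the shift from trial n-1 to n+1 is conditioned on the class
#' of trial n+2 rather than trial n. A causal trial-to-trial update acts
#' forwards in time only, so planted forward effects collapse toward zero
#' under this control.
#'
#' @inheritParams extract_triplets
#' @param n_boot,seed bootstrap settings, see [conditioned_shift()].
#' @return a `"shift_estimate"` (see [conditioned_shift()]).
#' @export
backwards_control <- function(trials, condition = "cued_success",
                              n_boot = 100, seed = 1L,
                              spec = window_spec(), classes = NULL) {
  if (inherits(trials, "reach_session")) trials <- trials$trials
  stopifnot(condition %in% c(trial_classes, "any", "any_reach"))
  n <- length(trials)
  if (is.null(classes)) classes <- classify_session(trials, spec)
  has_reach <- vapply(trials, function(tr) nrow(tr$reaches) > 0, TRUE)
  cond_ok <- switch(condition,
                    any = rep(TRUE, n),
                    any_reach = has_reach,
                    classes == condition)
  # j indexes the conditioning trial n+2; the measured pair is (j-3, j-1)
  j <- which(cond_ok & seq_len(n) >= 4L)
  tset <- structure(list(
    triplets = data.frame(n_minus = j - 3L, n = j - 2L, n_plus = j - 1L),
    condition = condition,
    inhibition_filter = "none",
    behavior = .trial_behavior(trials, spec),
    classes = classes,
    n_trials = n
  ), class = "triplet_set")
  conditioned_shift(tset, n_boot = n_boot, seed = seed)
}

#' Timing-resolved effect of inhibition on the behavioral update
#'
#' For each reach-time bin (relative to cue onset), selects triplets in
#' which trial n contains a successful reach inside the bin, splits them
#' by whether trial n carried optogenetic inhibition, and reports the
#' mean and standard error of the change in cued-window reach rate from
#' trial n-1 to trial n+1 in each group. The difference curve is indexed
#' by the lag between the midpoint of the inhibition window and the
#' midpoint of the reach bin.
#'
#' @param trials a [reach_session()] or list of trials (with inhibition
#'   windows on the inhibited trials).
#' @param reach_bins data.frame with columns `start` (bin start, seconds
#'   relative to cue) and `width` (bin length, seconds); mirrors the
#'   variable windows used in the published timing analysis (1.2 s before
#'   the cue, 0.2/0.5/1 s after).
#' @param spec a [window_spec()].
#' @param classes optional pre-computed classes (unused by the selection,
#'   which keys on successful reaches, but carried for bookkeeping).
#' @return data.frame with one row per bin: `bin_mid`, `window_s`,
#'   `n_control`, `n_inhibition`, `d_control`, `se_control`,
#'   `d_inhibition`, `se_inhibition`, `inh_mid`, `lag`
#'   (= `inh_mid - bin_mid`), `diff` (= inhibition - control). Bins with
#'   no triplets in a group have `NA` entries rather than zeros.
#' @export
timing_resolved_shift <- function(trials, reach_bins, spec = window_spec(),
                                  classes = NULL) {
  if (inherits(trials, "reach_session")) trials <- trials$trials
  stopifnot(all(c("start", "width") %in% names(reach_bins)))
  n <- length(trials)
  B <- .trial_behavior(trials, spec)
  has_inh <- vapply(trials, function(tr) !is.null(tr$inhibition_window), TRUE)
  inh_mid_all <- vapply(trials, function(tr) {
    if (is.null(tr$inhibition_window)) return(NA_real_)
    mean(tr$inhibition_window) - tr$t_cue
  }, 0)

  rows <- lapply(seq_len(nrow(reach_bins)), function(b) {
    w <- c(reach_bins$start[b], reach_bins$start[b] + reach_bins$width[b])
    hit <- vapply(seq_len(n), function(i) {
      tr <- trials[[i]]
      if (!tr$cue_present || !nrow(tr$reaches)) return(FALSE)
      rel <- tr$reaches$t_arm - tr$t_cue
      any(.in_half_open(rel, w) & tr$reaches$outcome == "success")
    }, TRUE)
    sel <- which(hit & seq_len(n) > 1L & seq_len(n) < n)
    grp <- function(idx) {
      if (!length(idx)) {
        return(c(d = NA_real_, se = NA_real_, m = 0))
      }
      d <- B[idx + 1L, "cued"] - B[idx - 1L, "cued"]
      c(d = mean(d), se = stats::sd(d) / sqrt(length(d)), m = length(d))
    }
    ctrl <- grp(sel[!has_inh[sel]])
    inh <- grp(sel[has_inh[sel]])
    inh_mid <- if (any(has_inh[sel])) mean(inh_mid_all[sel[has_inh[sel]]]) else NA_real_
    data.frame(bin_mid = mean(w), window_s = diff(w),
               n_control = ctrl["m"], n_inhibition = inh["m"],
               d_control = ctrl["d"], se_control = ctrl["se"],
               d_inhibition = inh["d"], se_inhibition = inh["se"],
               inh_mid = inh_mid, lag = inh_mid - mean(w),
               diff = inh["d"] - ctrl["d"], row.names = NULL)
  })
  do.call(rbind, rows)
}
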