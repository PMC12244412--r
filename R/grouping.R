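#' Smooth, normalize and concatenate the POP kernels of each unit
#'
#' For every unit, the four post-outcome kernels (success, failure,
#' cued success, cued failure) are smoothed with a centered boxcar of
#' `smooth_s` seconds, concatenated in that fixed order, and divided by
#' the maximum absolute value of the concatenation (so relative kernel
#' amplitudes are preserved; per-kernel normalization is available).
#' Units with no positive POP coefficient are excluded.
#'
#' @param kernels_by_unit named list of [extract_pop_kernels()] results
#'   (or bare 4 x n_lag matrices with rows in the standard order).
#' @param smooth_s boxcar width, seconds (default 0.08; narrower than one
#'   0.1-s bin, hence a no-op on the default lag grid).
#' @param bin_s lag-grid step of the kernels.
#' @param normalize `"global"` (one max over the concatenation) or
#'   `"per_kernel"`.
#' @return list with `vectors` (matrix, one row per kept unit),
#'   `unit_ids`, `excluded` (ids with no positive POP coefficient).
#' @export
prepare_kernel_vectors <- function(kernels_by_unit, smooth_s = 0.08,
                                   bin_s = 0.1,
                                   normalize = c("global", "per_kernel")) {
  normalize <- match.arg(normalize)
  ids <- names(kernels_by_unit)
  if (is.null(ids)) ids <- sprintf("u%03d", seq_along(kernels_by_unit))
  rows <- list()
  excluded <- character()
  for (i in seq_along(kernels_by_unit)) {
    k <- kernels_by_unit[[i]]
    if (inherits(k, "pop_kernels")) k <- k$kernels
    if (all(k <= 0)) {
      excluded <- c(excluded, ids[i])
      next
    }
    ks <- t(apply(k, 1, boxcar_smooth, width_s = smooth_s, bin_s = bin_s))
    if (normalize == "global") {
      v <- as.numeric(t(ks)) / max(abs(ks))
    } else {
      m <- apply(abs(ks), 1, max)
      m[m == 0] <- 1
      v <- as.numeric(t(ks / m))
    }
    rows[[ids[i]]] <- v
  }
  if (!length(rows)) {
    return(list(vectors = matrix(0, 0, 0), unit_ids = character(),
                excluded = excluded))
  }
  list(vectors = do.call(rbind, rows), unit_ids = names(rows),
       excluded = excluded)
}

#' Centered boxcar smoothing
#'
#' @param x numeric vector.
#' @param width_s boxcar width, seconds.
#' @param bin_s sample step, seconds.
#' @return smoothed vector (edges use the available samples).
#' @export
boxcar_smooth <- function(x, width_s, bin_s) {
  half <- floor(width_s / bin_s / 2)
  if (half < 1) return(x)
  w <- 2L * half + 1L
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Two-cluster k-means on kernel vectors
#'
#' @param vectors matrix, one unit per row (from
#'   [prepare_kernel_vectors()]).
#' @param seed integer seed.
#' @param restarts number of random initializations; the best by
#'   within-cluster sum of squares is kept.
#' @param m optional per-unit modulation indices used to canonicalize the
#'   labels (the cluster with the higher mean m becomes label 1);
#'   without `m`, the cluster containing the first row is label 1.
#' @return integer vector of labels (1/2) with attribute `centers`.
#' @export
kmeans_two <- function(vectors, seed = 1L, restarts = 20, m = NULL) {
  stopifnot(nrow(vectors) >= 2)
  if (nrow(unique(vectors)) < 2) {
    stop("all kernel vectors identical: no two-cluster structure")
  }
  set.seed(seed)
  km <- stats::kmeans(vectors, centers = 2, nstart = restarts)
  labels <- km$cluster
  flip <- if (!is.null(m)) {
    mean(m[labels == 2], na.rm = TRUE) > mean(m[labels == 1], na.rm = TRUE)
  } else {
    labels[1] == 2
  }
  if (flip) labels <- 3L - labels
  structure(labels, centers = km$centers)
}

#' Modulation index and sustained metric of a unit's POP kernels
#'
#' The modulation index `m` contrasts late against early post-success
#' coefficients, `m = (c_2to5 - c_0to2) / (|c_2to5| + |c_0to2|)`,
#' computed for the success and cued-success kernels and averaged; it
#' lies in `[-1, 1]`, negative when activity decays after a success. The
#' sustained metric `s = |c_1to5|` is computed for the failure and
#' cued-failure kernels and averaged; it is large for sustained
#' post-failure modulation.
#'
#' @param kernels a [extract_pop_kernels()] result (or bare 4 x n matrix
#'   with rows success, failure, cued_success, cued_failure).
#' @param lag_s lag grid, seconds (taken from the object when present).
#' @return list with `m` (NA when both averages are zero) and `s`.
#' @export
kernel_metrics <- function(kernels, lag_s = NULL) {
  if (inherits(kernels, "pop_kernels")) {
    lag_s <- kernels$lag_s
    kernels <- kernels$kernels
  }
  if (is.null(lag_s)) lag_s <- seq(0, by = 0.1, length.out = ncol(kernels))
  seg <- function(k, lo, hi, closed_hi = TRUE) {
    sel <- if (closed_hi) lag_s >= lo & lag_s <= hi else lag_s >= lo & lag_s < hi
    mean(k[sel])
  }
  m_one <- function(k) {
    c25 <- seg(k, 2, 5)
    c02 <- seg(k, 0, 2, closed_hi = FALSE)
    den <- abs(c25) + abs(c02)
    if (den == 0) return(NA_real_)
    (c25 - c02) / den
  }
  s_one <- function(k) abs(seg(k, 1, 5))
  m_vals <- c(m_one(kernels["success", ]), m_one(kernels["cued_success", ]))
  s_vals <- c(s_one(kernels["failure", ]), s_one(kernels["cued_failure", ]))
  list(m = mean(m_vals, na.rm = !all(is.na(m_vals))),
       s = mean(s_vals))
}

#' Fit the separating line in the (m, s) plane
#'
#' A two-class linear discriminant fitted to the training-set k-means
#' labels: the published analysis drew this boundary by hand between the
#' two clusters; here it is the pooled-covariance discriminant, which is
#' the line a linear classifier would draw. The frozen line then assigns
#' groups to any unit, including test-set units, without touching their
#' data. Units exactly on the line go to group 1.
#'
#' @param metrics data.frame with columns `m` and `s` (training units).
#' @param labels k-means labels (1/2) from [kmeans_two()].
#' @return object of class `"ms_boundary"`: list with `w` (normal
#'   vector), `c` (offset; group 1 iff `w . (m, s) - c >= 0`), `groups`
#'   (training assignment), `n_misassigned` (vs the k-means labels).
#' @export
boundary_assign <- function(metrics, labels) {
  stopifnot(all(c("m", "s") %in% names(metrics)),
            length(labels) == nrow(metrics), all(labels %in% 1:2))
  X <- cbind(metrics$m, metrics$s)
  ok <- stats::complete.cases(X)
  X1 <- X[ok & labels == 1, , drop = FALSE]
  X2 <- X[ok & labels == 2, , drop = FALSE]
  if (!nrow(X1) || !nrow(X2)) stop("both clusters must be non-empty")
  mu1 <- colMeans(X1)
  mu2 <- colMeans(X2)
  pool <- (crossprod(scale(X1, center = TRUE, scale = FALSE)) +
             crossprod(scale(X2, center = TRUE, scale = FALSE))) /
    max(1, nrow(X1) + nrow(X2) - 2)
  pool <- pool + diag(1e-8, 2)
  w <- solve(pool, mu1 - mu2)
  c0 <- sum(w * (mu1 + mu2)) / 2
  b <- structure(list(w = as.numeric(w), c = c0), class = "ms_boundary")
  groups <- predict_boundary(b, metrics)
  b$groups <- groups
  b$n_misassigned <- sum(groups[ok] != labels[ok])
  b
}

#' Assign groups from a frozen (m, s) boundary
#'
#' @param boundary an [boundary_assign()] result.
#' @param metrics data.frame with columns `m`, `s`.
#' @return integer vector of groups (1/2; NA where m is undefined).
#' @export
predict_boundary <- function(boundary, metrics) {
  stopifnot(inherits(boundary, "ms_boundary"))
  score <- boundary$w[1] * metrics$m + boundary$w[2] * metrics$s - boundary$c
  ifelse(is.na(score), NA_integer_, ifelse(score >= 0, 1L, 2L))
}
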