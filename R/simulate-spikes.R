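#' Default event-kernel templates for the two planted unit groups
#'
#' Group 1 emulates units whose firing is elevated immediately after a
#' success and decays over the post-outcome period (a negative modulation
#' index); group 2 emulates units with a slowly rising, sustained response
#' after failures (a large sustained metric); "other" units carry no
#' outcome kernels. Kernels are in Hz on the design lag grid and are zero
#' at negative lags.
#'
#' @param design an [event_design()].
#' @param amp_success peak of the group-1 post-success response, Hz.
#' @param amp_failure plateau of the group-2 post-failure response, Hz.
#' @return named list (`group1`, `group2`, `other`) of channel x lag
#'   kernel matrices.
#' @export
default_kernel_templates <- function(design = event_design(),
                                     amp_success = 6, amp_failure = 4) {
  lags <- design$lags
  nl <- length(lags)
  blank <- matrix(0, length(design$channels), nl,
                  dimnames = list(design$channels, NULL))
  post <- lags >= 0
  early_decay <- ifelse(post, exp(-lags / 0.8), 0)          # fades by ~2 s
  sustained <- ifelse(post, pmin(lags / 1.0, 1), 0)         # ramps to plateau
  g1 <- blank
  g1["success", ] <- amp_success * early_decay
  g1["cued_success", ] <- 0.5 * amp_success * early_decay
  g1["cue", ] <- 0.5 * ifelse(post & lags < 0.5, 1, 0)
  g2 <- blank
  g2["failure_drop", ] <- amp_failure * sustained
  g2["failure_pellet_missing", ] <- amp_failure * sustained
  g2["cued_failure_drop", ] <- 0.5 * amp_failure * sustained
  g2["cued_failure_pellet_missing", ] <- 0.5 * amp_failure * sustained
  list(group1 = g1, group2 = g2, other = blank)
}

#' Configuration for the synthetic spike-train generator
#'
#' @param n_units number of units.
#' @param group_fractions named fractions (`group1`, `group2`, `other`)
#'   summing to 1.
#' @param templates kernel templates, see [default_kernel_templates()].
#' @param baseline_range SPN-like baseline rates, Hz (uniform draw).
#' @param width_range waveform widths at half-maximum, ms (uniform draw;
#'   the default range classifies every unit as a putative SPN at
#'   SPN-like rates).
#' @param kernel_jitter_sd per-unit multiplicative jitter (lognormal SD)
#'   applied to its group template.
#' @param design the [event_design()] grid the kernels live on.
#' @return list of class `"spike_gen_config"`.
#' @export
spike_gen_config <- function(n_units = 40,
                             group_fractions = c(group1 = 0.45,
                                                 group2 = 0.45,
                                                 other = 0.10),
                             templates = default_kernel_templates(),
                             baseline_range = c(1, 3),
                             width_range = c(0.25, 0.45),
                             kernel_jitter_sd = 0.15,
                             design = event_design()) {
  stopifnot(abs(sum(group_fractions) - 1) < 1e-9,
            all(group_fractions >= 0),
            all(sort(names(group_fractions)) == sort(names(templates))),
            baseline_range[1] >= 0, baseline_range[1] <= baseline_range[2])
  structure(as.list(environment()), class = "spike_gen_config")
}

#' Generate a population of synthetic spike trains
#'
#' Each unit's rate is `baseline + sum over events of kernel(t - t_event)`
#' (the linear-link generative model behind the event GLM), floored at
#' zero; spikes are drawn as an inhomogeneous Poisson process that is
#' piecewise constant on the design bins. Units are assigned to the
#' planted kernel groups in proportion to `group_fractions`.
#'
#' @param session a [reach_session()] providing the behavioral events.
#' @param cfg a [spike_gen_config()].
#' @param seed integer seed.
#' @return list with `units` (list of [unit_recording()]), `truth` (per
#'   unit: group label, kernel matrix, baseline; plus `n_rate_floor_bins`
#'   counting floored bins) and `duration_s`.
#' @export
generate_population_spikes <- function(session, cfg = spike_gen_config(),
                                       seed = 1L) {
  stopifnot(inherits(session, "reach_session"),
            inherits(cfg, "spike_gen_config"))
  set.seed(seed)
  duration <- max(vapply(session$trials, `[[`, 0, "trial_end"))
  events <- session_event_channels(session)
  X <- build_design(events, duration, cfg$design)
  bin <- cfg$design$bin_s
  n_bins <- nrow(X)

  counts <- floor(cfg$group_fractions * cfg$n_units)
  short <- cfg$n_units - sum(counts)
  if (short > 0) {
    frac <- cfg$group_fractions * cfg$n_units - counts
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[top] <- counts[top] + 1L
  }
  groups <- sample(rep(names(counts), times = counts))

  units <- vector("list", cfg$n_units)
  truth <- vector("list", cfg$n_units)
  floor_bins <- 0L
  for (u in seq_len(cfg$n_units)) {
    g <- groups[u]
    jit <- exp(stats::rnorm(1, 0, cfg$kernel_jitter_sd))
    kern <- cfg$templates[[g]] * jit
    baseline <- stats::runif(1, cfg$baseline_range[1], cfg$baseline_range[2])
    beta <- as.numeric(t(kern))  # event-major, lag-minor: matches columns
    rate <- baseline + as.numeric(X %*% beta)
    neg <- rate < 0
    floor_bins <- floor_bins + sum(neg)
    rate[neg] <- 0
    counts <- stats::rpois(n_bins, rate * bin)
    spikes <- rep((seq_len(n_bins) - 1) * bin, counts) +
      stats::runif(sum(counts), 0, bin)
    width <- stats::runif(1, cfg$width_range[1], cfg$width_range[2])
    units[[u]] <- unit_recording(sprintf("u%03d", u), sort(spikes),
                                 width_hm = width, duration_s = duration)
    truth[[u]] <- list(unit_id = sprintf("u%03d", u), group = g,
                       kernels = kern, baseline = baseline)
  }
  if (floor_bins > 0) {
    warning(sprintf("linear-link rate floored at 0 in %d bins", floor_bins))
  }
  list(units = units,
       truth = list(config = cfg, seed = seed, units = truth,
                    groups = stats::setNames(groups,
                                             vapply(truth, `[[`, "", "unit_id")),
                    n_rate_floor_bins = floor_bins),
       duration_s = duration)
}
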