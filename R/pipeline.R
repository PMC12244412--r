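#' Run the end-to-end synthetic analysis pipeline
#'
#' Orchestrates a full run from synthetic generation through every
#' analysis stage, writing tidy CSV artifacts and a JSON run manifest
#' (configuration snapshot, per-stage seeds, file digests, package
#' version, stage timings) that fully determines the outputs.
#'
#' @param config named list (or path to a YAML file) with optional
#'   entries `stages` (subset of `c("session", "behavior", "reinforce",
#'   "spikes", "glm", "group", "tensor", "decode", "photometry")`),
#'   `behavior` / `spikes` / `photometry` (argument lists for the
#'   generator configs), `n_boot`, `glm` (argument list for
#'   [glm_config()]), `tensor` (list with `ranks`, `runs_per_rank`).
#'   Stages that depend on a skipped stage are skipped with a notice.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it.
#' @return invisibly, the manifest (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("cuedreach-run-"),
                         seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  all_stages <- c("session", "behavior", "reinforce", "spikes", "glm",
                  "group", "tensor", "decode", "photometry")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(package_version = as.character(utils::packageVersion("cuedreach")),
                   master_seed = seed, stages = stages, seeds = list(),
                   timings_s = list(), files = list(), notices = character())
  tic <- function() proc.time()[["elapsed"]]
  note <- function(msg) {
    manifest$notices <<- c(manifest$notices, msg)
    message(msg)
  }
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    manifest$files[[name]] <<- unname(tools::md5sum(path))
    path
  }
  skip_if_missing <- function(stage, needs, have) {
    missing <- setdiff(needs, have)
    if (length(missing)) {
      note(sprintf("stage '%s' skipped: requires %s", stage,
                   paste(missing, collapse = ", ")))
      return(TRUE)
    }
    FALSE
  }

  done <- character()
  gen <- NULL; spikes <- NULL; glm_fits <- NULL; groups <- NULL
  split <- NULL; trials_df <- NULL

  if ("session" %in% stages) {
    t0 <- tic()
    manifest$seeds$session <- seed
    cfg_b <- do.call(behavior_gen_config, config$behavior %||% list())
    gen <- generate_session(cfg_b, seed = seed)
    emit("session.csv", function(p) write_session_csv(gen$session, p))
    manifest$timings_s$session <- tic() - t0
    done <- c(done, "session")
  }

  if ("behavior" %in% stages && !skip_if_missing("behavior", "session", done)) {
    t0 <- tic()
    d <- dprime(gen$session)
    classes <- classify_session(gen$session)
    emit("behavior.csv", function(p) {
      utils::write.csv(data.frame(
        trial_id = vapply(gen$session$trials, `[[`, 0L, "trial_id"),
        class = classes), p, row.names = FALSE)
    })
    emit("behavior_summary.csv", function(p) {
      utils::write.csv(data.frame(
        dprime = d$dprime, hit_rate = d$hit_rate,
        stage = learning_stage(d$dprime),
        learned = session_learned(gen$session)$learned), p, row.names = FALSE)
    })
    manifest$timings_s$behavior <- tic() - t0
    done <- c(done, "behavior")
  }

  if ("reinforce" %in% stages && !skip_if_missing("reinforce", "session", done)) {
    t0 <- tic()
    manifest$seeds$reinforce <- seed + 1L
    tset <- extract_triplets(gen$session, "cued_success")
    if (nrow(tset$triplets)) {
      sh <- conditioned_shift(tset, n_boot = config$n_boot %||% 100,
                              seed = seed + 1L)
      emit("shift_draws.csv", function(p) {
        utils::write.csv(cbind(condition = tset$condition, sh$draws), p,
                         row.names = FALSE)
      })
    } else {
      note("stage 'reinforce': no cued-success triplets in this session")
    }
    manifest$timings_s$reinforce <- tic() - t0
    done <- c(done, "reinforce")
  }

  if ("spikes" %in% stages && !skip_if_missing("spikes", "session", done)) {
    t0 <- tic()
    manifest$seeds$spikes <- seed + 2L
    cfg_s <- do.call(spike_gen_config, config$spikes %||% list())
    spikes <- generate_population_spikes(gen$session, cfg_s, seed = seed + 2L)
    emit("units_meta.csv", function(p) {
      write_units_csv(spikes$units, file.path(out_dir, "spikes.csv"), p)
    })
    manifest$files[["spikes.csv"]] <-
      unname(tools::md5sum(file.path(out_dir, "spikes.csv")))
    # one stratified split shared by every downstream neural stage
    classes <- classify_session(gen$session)
    t_arm_of <- vapply(seq_along(gen$session$trials), function(i) {
      outcome_reach_time(gen$session$trials[[i]], classes[i])
    }, 0)
    keep <- classes %in% tensor_conditions_map() & !is.na(t_arm_of)
    trials_df <- data.frame(
      trial_id = vapply(gen$session$trials, `[[`, 0L, "trial_id")[keep],
      condition = unname(vapply(classes[keep], map_class_to_condition, "")),
      t_arm = t_arm_of[keep])
    ids <- split(trials_df$trial_id, trials_df$condition)
    split <- train_test_split(ids, seed = seed + 3L)
    manifest$seeds$split <- seed + 3L
    manifest$timings_s$spikes <- tic() - t0
    done <- c(done, "spikes")
  }

  if ("glm" %in% stages && !skip_if_missing("glm", "spikes", done)) {
    t0 <- tic()
    duration <- spikes$duration_s
    X <- build_design(session_event_channels(gen$session), duration)
    cfg_g <- do.call(glm_config, config$glm %||% list(alpha_grid = c(0, 0.01)))
    glm_fits <- lapply(spikes$units, function(u) {
      fit_glm(X, bin_spikes(u$spike_times, duration), cfg_g)
    })
    names(glm_fits) <- vapply(spikes$units, `[[`, "", "unit_id")
    emit("glm_kernels.csv", function(p) {
      rows <- do.call(rbind, lapply(names(glm_fits), function(id) {
        f <- glm_fits[[id]]
        data.frame(unit_id = id,
                   event = rep(rownames(f$coefficients),
                               times = ncol(f$coefficients)),
                   lag_s = rep(f$design$lags,
                               each = nrow(f$coefficients)),
                   coefficient = as.numeric(f$coefficients))
      }))
      utils::write.csv(rows, p, row.names = FALSE)
    })
    manifest$timings_s$glm <- tic() - t0
    done <- c(done, "glm")
  }

  if ("group" %in% stages && !skip_if_missing("group", "glm", done)) {
    t0 <- tic()
    pop <- lapply(glm_fits, extract_pop_kernels)
    prep <- prepare_kernel_vectors(pop)
    if (nrow(prep$vectors) >= 2) {
      mets <- lapply(pop[prep$unit_ids], kernel_metrics)
      mdf <- data.frame(unit_id = prep$unit_ids,
                        m = vapply(mets, `[[`, 0, "m"),
                        s = vapply(mets, `[[`, 0, "s"))
      labels <- kmeans_two(prep$vectors, seed = seed + 4L, m = mdf$m)
      manifest$seeds$group <- seed + 4L
      boundary <- boundary_assign(mdf, labels)
      groups <- stats::setNames(boundary$groups, prep$unit_ids)
      emit("unit_groups.csv", function(p) {
        utils::write.csv(cbind(mdf, kmeans_label = labels,
                               group = boundary$groups), p, row.names = FALSE)
      })
      manifest$boundary <- list(w = boundary$w, c = boundary$c)
    } else {
      note("stage 'group': too few units with positive POP coefficients")
    }
    manifest$timings_s$group <- tic() - t0
    done <- c(done, "group")
  }

  split_trials <- function(which_half) {
    ids <- unlist(lapply(split, `[[`, which_half), use.names = FALSE)
    trials_df[trials_df$trial_id %in% ids, ]
  }

  if ("tensor" %in% stages && !skip_if_missing("tensor", "spikes", done)) {
    t0 <- tic()
    manifest$seeds$tensor <- seed + 5L
    train <- split_trials("train")
    if (all(table(train$condition) > 0) &&
        length(unique(train$condition)) == 4) {
      tt <- trial_tensor(spikes$units, train)
      tensor <- build_tensor(tt)
      tcfg <- config$tensor %||% list()
      sel <- select_model(tensor, ranks = tcfg$ranks %||% 1:2,
                          runs_per_rank = tcfg$runs_per_rank %||% 3,
                          chosen_rank = 2, seed = seed + 5L)
      emit("tensor_diagnostics.csv", function(p) {
        utils::write.csv(sel$diagnostics, p, row.names = FALSE)
      })
      emit("tensor_factors.csv", function(p) {
        m <- sel$model
        utils::write.csv(data.frame(
          factor = rep(seq_len(m$rank), each = nrow(m$A)),
          unit_id = rep(tensor$unit_ids, m$rank),
          loading = as.numeric(m$A)), p, row.names = FALSE)
      })
    } else {
      note("stage 'tensor': a behavioral condition has no training trials")
    }
    manifest$timings_s$tensor <- tic() - t0
    done <- c(done, "tensor")
  }

  if ("decode" %in% stages &&
      !skip_if_missing("decode", c("spikes", "group"), done) &&
      !is.null(groups)) {
    t0 <- tic()
    manifest$seeds$decode <- seed + 6L
    test <- split_trials("test")
    if (length(unique(test$condition)) == 4) {
      keep_units <- spikes$units[vapply(spikes$units, `[[`, "", "unit_id")
                                 %in% names(groups)]
      rates <- pop_rates(keep_units, test)
      pts <- bootstrap_scatter(rates, unname(groups[rates$unit_ids]),
                               n = config$decode_n %||% 20,
                               seed = seed + 6L)
      acc <- lda_accuracy(pts)
      sh <- shuffle_controls(rates, unname(groups[rates$unit_ids]),
                             "shuffle_condition_labels",
                             n = config$decode_n %||% 20, seed = seed + 6L)
      emit("decode_points.csv", function(p) {
        utils::write.csv(pts, p, row.names = FALSE)
      })
      emit("decode_accuracy.csv", function(p) {
        utils::write.csv(data.frame(real = acc, label_shuffle = sh), p,
                         row.names = FALSE)
      })
    } else {
      note("stage 'decode': a behavioral condition has no test trials")
    }
    manifest$timings_s$decode <- tic() - t0
    done <- c(done, "decode")
  }

  if ("photometry" %in% stages &&
      !skip_if_missing("photometry", "session", done)) {
    t0 <- tic()
    manifest$seeds$photometry <- seed + 7L
    cfg_p <- do.call(photometry_gen_config, config$photometry %||% list())
    # keep the demo trace short: the first 120 s of the session
    sub <- Filter(function(tr) tr$trial_end <= 120, gen$session$trials)
    if (length(sub) >= 3) {
      phot <- generate_photometry(reach_session(sub), cfg = cfg_p,
                                  seed = seed + 7L)
      pw <- demodulate(phot$trace)
      zz <- rolling_zscore(pw)
      emit("photometry_z.csv", function(p) {
        utils::write.csv(data.frame(time_s = zz$time_s, z = zz$z), p,
                         row.names = FALSE)
      })
    } else {
      note("stage 'photometry': session too short for the demo trace")
    }
    manifest$timings_s$photometry <- tic() - t0
    done <- c(done, "photometry")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# internal: which trial classes feed the neural analyses, and their
# tensor condition names
tensor_conditions_map <- function() {
  c("cued_success", "cued_failure", "uncued_success", "uncued_failure")
}

map_class_to_condition <- function(cls) {
  switch(cls,
         cued_success = "cued_success",
         cued_failure = "cued_failure",
         uncued_success = "success",
         uncued_failure = "failure",
         stop("not a tensor condition class: ", cls))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
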