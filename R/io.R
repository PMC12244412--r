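#' Write a session as a tidy event table (CSV)
#'
#' One row per event with columns `trial_id` (0-based), `event_type`
#' (`trial_start`, `trial_end`, `cue`, `pellet`, `reach`, `distractor`,
#' `inhibition_on`, `inhibition_off`), `time_s` (6 decimal places),
#' `outcome` (reach rows only) and `flags` (semicolon-separated:
#' `catch`, `chewing`, `no_pellet`). The round trip through
#' [read_session_csv()] is lossless at the serialized precision.
#'
#' @param session a [reach_session()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "reach_session"))
  rows <- list()
  add <- function(trial_id, type, time, outcome = "", flags = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      trial_id = trial_id, event_type = type,
      time_s = sprintf("%.6f", time), outcome = outcome, flags = flags,
      stringsAsFactors = FALSE)
  }
  for (tr in session$trials) {
    id <- tr$trial_id
    flags <- c(if (tr$catch) "catch", if (tr$chewing_at_start) "chewing",
               if (!tr$pellet_presented) "no_pellet")
    add(id, "trial_start", tr$trial_start, flags = paste(flags, collapse = ";"))
    if (tr$cue_present) add(id, "cue", tr$t_cue)
    if (tr$pellet_presented && tr$cue_present) add(id, "pellet", tr$t_cue)
    for (dt in tr$distractor_times) add(id, "distractor", dt)
    if (!is.null(tr$inhibition_window)) {
      add(id, "inhibition_on", tr$inhibition_window[1])
      add(id, "inhibition_off", tr$inhibition_window[2])
    }
    if (nrow(tr$reaches)) {
      for (k in seq_len(nrow(tr$reaches))) {
        add(id, "reach", tr$reaches$t_arm[k], outcome = tr$reaches$outcome[k])
      }
    }
    add(id, "trial_end", tr$trial_end)
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session from a tidy event table (CSV)
#'
#' @param path file written by [write_session_csv()].
#' @param mouse_id,session_id optional identifiers for the result.
#' @return a [reach_session()].
#' @export
read_session_csv <- function(path, mouse_id = NA_character_,
                             session_id = NA_character_) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(trial_id = "integer",
                                        event_type = "character",
                                        time_s = "numeric",
                                        outcome = "character",
                                        flags = "character"))
  known <- c("trial_start", "trial_end", "cue", "pellet", "reach",
             "distractor", "inhibition_on", "inhibition_off")
  bad <- which(!tab$event_type %in% known)
  if (length(bad)) {
    stop("unknown event_type at row(s): ", paste(utils::head(bad), collapse = ", "))
  }
  bad_outcome <- which(tab$event_type == "reach" &
                         !tab$outcome %in% reach_outcomes)
  if (length(bad_outcome)) {
    stop("unknown reach outcome at row(s): ",
         paste(utils::head(bad_outcome), collapse = ", "))
  }
  trials <- lapply(sort(unique(tab$trial_id)), function(id) {
    rows <- tab[tab$trial_id == id, ]
    one <- function(type) {
      v <- rows$time_s[rows$event_type == type]
      if (length(v)) v[1] else NA_real_
    }
    start_row <- rows[rows$event_type == "trial_start", ][1, ]
    flags <- strsplit(start_row$flags, ";", fixed = TRUE)[[1]]
    rch <- rows[rows$event_type == "reach", ]
    if (is.unsorted(rch$time_s)) {
      stop("unordered reach events in trial ", id)
    }
    t_cue <- one("cue")
    inh_on <- one("inhibition_on")
    trial(trial_start = one("trial_start"), trial_end = one("trial_end"),
          t_cue = t_cue, cue_present = !is.na(t_cue),
          pellet_presented = !"no_pellet" %in% flags,
          catch = "catch" %in% flags,
          chewing_at_start = "chewing" %in% flags,
          inhibition_window = if (!is.na(inh_on)) c(inh_on, one("inhibition_off")),
          distractor_times = rows$time_s[rows$event_type == "distractor"],
          reaches = reaches(rch$time_s, rch$outcome),
          trial_id = id)
  })
  reach_session(trials, mouse_id = mouse_id, session_id = session_id)
}

#' Write / read a session as hierarchical JSON
#'
#' @param session a [reach_session()].
#' @param path output file.
#' @return the path (write) or a [reach_session()] (read).
#' @export
write_session_json <- function(session, path) {
  stopifnot(inherits(session, "reach_session"))
  obj <- list(mouse_id = session$mouse_id, session_id = session$session_id,
              trials = lapply(session$trials, function(tr) {
                list(trial_id = tr$trial_id, trial_start = tr$trial_start,
                     trial_end = tr$trial_end, t_cue = tr$t_cue,
                     cue_present = tr$cue_present,
                     pellet_presented = tr$pellet_presented,
                     catch = tr$catch,
                     chewing_at_start = tr$chewing_at_start,
                     inhibition_window = tr$inhibition_window,
                     distractor_times = tr$distractor_times,
                     reaches = tr$reaches)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_session_json
#' @export
read_session_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trials <- lapply(seq_len(nrow(obj$trials)), function(i) {
    row <- obj$trials[i, ]
    rch <- row$reaches[[1]]
    if (is.null(rch) || !length(rch)) rch <- reaches()
    inh <- unlist(row$inhibition_window)
    trial(trial_start = row$trial_start, trial_end = row$trial_end,
          t_cue = if (is.null(row$t_cue) || is.na(row$t_cue)) NA_real_ else row$t_cue,
          cue_present = isTRUE(row$cue_present),
          pellet_presented = isTRUE(row$pellet_presented),
          catch = isTRUE(row$catch),
          chewing_at_start = isTRUE(row$chewing_at_start),
          inhibition_window = if (length(inh) == 2) as.numeric(inh),
          distractor_times = unlist(row$distractor_times),
          reaches = reaches(rch$t_arm, rch$outcome),
          trial_id = row$trial_id)
  })
  reach_session(trials,
                mouse_id = if (is.null(obj$mouse_id)) NA_character_ else obj$mouse_id,
                session_id = if (is.null(obj$session_id)) NA_character_ else obj$session_id)
}

#' Write unit recordings as spike + metadata tables
#'
#' @param units list of [unit_recording()] objects.
#' @param spike_path CSV of (`unit_id`, `spike_time_s`).
#' @param meta_path CSV of (`unit_id`, `width_ms`, `mean_rate_hz`,
#'   `duration_s`, `unit_class`).
#' @return invisibly, the two paths.
#' @export
write_units_csv <- function(units, spike_path, meta_path) {
  spikes <- do.call(rbind, lapply(units, function(u) {
    if (!length(u$spike_times)) return(NULL)
    data.frame(unit_id = u$unit_id,
               spike_time_s = sprintf("%.6f", u$spike_times))
  }))
  meta <- do.call(rbind, lapply(units, function(u) {
    data.frame(unit_id = u$unit_id, width_ms = u$width_hm,
               mean_rate_hz = u$mean_rate, duration_s = u$duration_s,
               unit_class = u$unit_class)
  }))
  utils::write.csv(spikes, spike_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(spike_path, meta_path))
}

#' Read unit recordings from spike + metadata tables
#'
#' Spike times are sorted on read (with a warning when the file was
#' unsorted) and the stored unit class is cross-checked against the
#' class recomputed from width and rate.
#'
#' @param spike_path,meta_path files written by [write_units_csv()].
#' @return list of [unit_recording()] objects.
#' @export
read_units_csv <- function(spike_path, meta_path) {
  if (!file.exists(spike_path)) stop("spike table not found: ", spike_path)
  spikes <- utils::read.csv(spike_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    sp <- spikes$spike_time_s[spikes$unit_id == row$unit_id]
    if (is.unsorted(sp)) {
      warning("unsorted spike times for ", row$unit_id, "; sorting")
      sp <- sort(sp)
    }
    u <- unit_recording(row$unit_id, sp, width_hm = row$width_ms,
                        duration_s = row$duration_s,
                        mean_rate = row$mean_rate_hz)
    if (!is.null(row$unit_class) && !is.na(row$unit_class) &&
        row$unit_class != u$unit_class) {
      warning(sprintf("stored class '%s' for %s differs from recomputed '%s'",
                      row$unit_class, row$unit_id, u$unit_class))
    }
    u
  })
}
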