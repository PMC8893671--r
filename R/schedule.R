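## Trial scheduling: BIDS-style events tables on the TR grid.
##
## Trial types: Id-PS / Mod-PS passive stimulus (2 s cue + 2-6 s ITI),
## Id-CR cued recall (2 s cue + 2 s cue-response + 8 s recall + 2-6 s ITI,
## represented as separate Id-CR-cue and Id-CR-recall rows), and Mod-FS
## feedback-triggered stimulus trials of fixed total length.

TRIAL_TYPES <- c("Id-PS", "Id-CR-cue", "Id-CR-recall", "Mod-PS", "Mod-FS")

validate_schedule <- function(schedule, tr = NULL, scan_duration = NULL) {
  req <- c("onset", "duration", "trial_type", "stim_id")
  if (!is.data.frame(schedule) || !all(req %in% names(schedule))) {
    stop("schedule must have columns onset, duration, trial_type, stim_id",
         call. = FALSE)
  }
  if (any(diff(schedule$onset) <= 0)) {
    stop("schedule onsets must be strictly increasing", call. = FALSE)
  }
  if (any(schedule$duration <= 0)) {
    stop("schedule durations must be positive", call. = FALSE)
  }
  if (!all(schedule$trial_type %in% TRIAL_TYPES)) {
    stop("unknown trial_type in schedule", call. = FALSE)
  }
  if (!is.null(tr)) {
    k <- schedule$onset / tr
    if (any(abs(k - round(k)) > 1e-9)) {
      stop("schedule onsets must be aligned to the TR grid", call. = FALSE)
    }
  }
  if (!is.null(scan_duration) &&
      any(schedule$onset + schedule$duration > scan_duration + 1e-9)) {
    stop("schedule extends past scan length", call. = FALSE)
  }
  invisible(schedule)
}

## sample a TR-aligned inter-trial interval uniformly from 2-6 s
sample_iti <- function(n, tr) tr * sample(seq(2 / tr, 6 / tr), n, replace = TRUE)

## Build one run's schedule from an ordered vector of trial descriptors:
## list(type = "PS"/"CR"/"FS", stim_id). Returns the events data.frame.
build_run_schedule <- function(order, tr, fs_length) {
  rows <- list()
  t <- 0
  iti <- sample_iti(length(order), tr)
  for (j in seq_along(order)) {
    tr_type <- order[[j]]$type
    sid <- order[[j]]$stim_id
    if (tr_type %in% c("Id-PS", "Mod-PS")) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset = t, duration = 2, trial_type = tr_type, stim_id = sid,
        stringsAsFactors = FALSE)
      t <- t + 2 + iti[j]
    } else if (tr_type == "Id-CR") {
      rows[[length(rows) + 1L]] <- data.frame(
        onset = t, duration = 2, trial_type = "Id-CR-cue", stim_id = sid,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        onset = t + 4, duration = 8, trial_type = "Id-CR-recall",
        stim_id = sid, stringsAsFactors = FALSE)
      t <- t + 12 + iti[j]
    } else if (tr_type == "Mod-FS") {
      rows[[length(rows) + 1L]] <- data.frame(
        onset = t, duration = fs_length, trial_type = "Mod-FS", stim_id = sid,
        stringsAsFactors = FALSE)
      t <- t + fs_length
    } else {
      stop("unknown trial descriptor type: ", tr_type, call. = FALSE)
    }
  }
  do.call(rbind, rows)
}

## max absolute pairwise correlation between per-type unit HRF regressors
order_badness <- function(schedule, tr, n_vols) {
  types <- unique(schedule$trial_type)
  if (length(types) < 2) return(0)
  regs <- sapply(types, function(ty) {
    on <- schedule$onset[schedule$trial_type == ty]
    imp <- numeric(n_vols)
    imp[round(on / tr) + 1L] <- 1
    convolve_hrf(imp, tr)
  })
  cm <- abs(cor(regs))
  max(cm[upper.tri(cm)])
}

## choose among `n_cand` seeded shuffles the trial order whose trial-type
## HRF regressors are least correlated (the published orders are fixed but
## unavailable, so orders are regenerated under this criterion)
best_order <- function(descriptors, tr, n_vols, fs_length, n_cand = 20) {
  best <- NULL
  best_bad <- Inf
  for (k in seq_len(n_cand)) {
    ord <- sample(descriptors)
    sched <- build_run_schedule(ord, tr, fs_length)
    bad <- order_badness(sched, tr, n_vols)
    if (bad < best_bad) {
      best_bad <- bad
      best <- sched
    }
  }
  best
}

#' Build Identification-task run schedules
#'
#' Distributes passive-stimulus and cued-recall trials over runs in a
#' pseudo-random order chosen to minimize correlation between the
#' trial-type HRF regressors.
#'
#' @param ps_stim,cr_stim Character vectors of stimulus ids for Id-PS and
#'   Id-CR trials (defaults match the 90 + 30 design over 2 runs).
#' @param tr Repetition time, seconds.
#' @param n_runs Number of runs.
#' @param run_duration Run length in seconds (default 564, i.e. 9.4 min).
#' @param seed Integer seed.
#' @return List of events `data.frame`s, one per run.
#' @export
make_id_schedule <- function(ps_stim, cr_stim, tr = 2, n_runs = 2,
                             run_duration = 564, seed = NULL) {
  with_seed(seed, {
    ps_split <- split(ps_stim, rep(seq_len(n_runs), length.out = length(ps_stim)))
    cr_split <- split(cr_stim, rep(seq_len(n_runs), length.out = length(cr_stim)))
    lapply(seq_len(n_runs), function(r) {
      desc <- c(
        lapply(ps_split[[r]], function(s) list(type = "Id-PS", stim_id = s)),
        lapply(cr_split[[r]], function(s) list(type = "Id-CR", stim_id = s))
      )
      sched <- best_order(desc, tr, round(run_duration / tr), fs_length = NA)
      validate_schedule(sched, tr = tr, scan_duration = run_duration)
    })
  })
}

#' Build Modulation-task run schedules
#'
#' Interleaves passive-stimulus trials with fixed-length feedback-triggered
#' trials, again minimizing trial-type regressor correlation.
#'
#' @param ps_stim,fs_stim Stimulus ids assigned to Mod-PS and Mod-FS
#'   trials.
#' @param tr Repetition time, seconds.
#' @param n_runs Number of runs.
#' @param run_duration Run length in seconds (default 630, i.e. 10.5 min).
#' @param fs_length Fixed Mod-FS trial length in seconds (default 44).
#' @param seed Integer seed.
#' @return List of events `data.frame`s, one per run.
#' @export
make_mod_schedule <- function(ps_stim, fs_stim, tr = 2, n_runs = 2,
                              run_duration = 630, fs_length = 44,
                              seed = NULL) {
  with_seed(seed, {
    ps_split <- split(ps_stim, rep(seq_len(n_runs), length.out = length(ps_stim)))
    fs_split <- split(fs_stim, rep(seq_len(n_runs), length.out = length(fs_stim)))
    lapply(seq_len(n_runs), function(r) {
      desc <- c(
        lapply(ps_split[[r]], function(s) list(type = "Mod-PS", stim_id = s)),
        lapply(fs_split[[r]], function(s) list(type = "Mod-FS", stim_id = s))
      )
      sched <- best_order(desc, tr, round(run_duration / tr), fs_length)
      validate_schedule(sched, tr = tr, scan_duration = run_duration)
    })
  })
}

#' Read / write a trial schedule as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type`, `stim_id`; onsets in seconds,
#' 0-based from scan start.
#'
#' @param schedule Events `data.frame`.
#' @param path File path.
#' @return `read_events_tsv()` returns the events `data.frame`;
#'   `write_events_tsv()` returns `path` invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  validate_schedule(schedule)
  write.table(schedule, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  schedule <- read.delim(path, stringsAsFactors = FALSE)
  schedule$stim_id <- as.character(schedule$stim_id)
  validate_schedule(schedule)
  schedule
}
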