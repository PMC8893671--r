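#' Volume-series container
#'
#' A voxel-by-time matrix of preprocessed signal in percent-signal-change
#' units, with acquisition metadata.
#'
#' @param data Numeric matrix, voxels in rows, volumes in columns.
#' @param tr Repetition time in seconds (default 2).
#' @param t0 Acquisition start time in seconds (default 0).
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr = 2, t0 = 0) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("'data' must be a numeric matrix (voxels x time)", call. = FALSE)
  }
  if (anyNA(data)) stop("volume series must not contain NA", call. = FALSE)
  assert_scalar_number(tr, "tr", lower = 1e-6)
  structure(list(data = data, tr = tr, t0 = t0), class = "volume_series")
}

#' @exportS3Method base::print
print.volume_series <- function(x, ...) {
  cat(sprintf("<volume_series: %d voxels x %d volumes, tr=%gs>\n",
              nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

## per-TR valence/arousal neural amplitude trains for a schedule.
## Single-impulse events (passive cues, recall cue) go on the unit-peak
## kernel train; sustained activity (recall window, self-induction) goes on
## the unit-sum kernel train so that a held level L produces a steady-state
## response of L.
schedule_amplitudes <- function(schedule, catalog, n_vols, tr,
                                regulation_valence = 0.33,
                                regulation_arousal = 0.33,
                                selfinduction = NULL) {
  score <- function(ids, col) {
    i <- match(ids, catalog$stim_id)
    if (anyNA(i)) stop("schedule stimulus missing from catalog", call. = FALSE)
    catalog[[col]][i]
  }
  gain <- if ("gain" %in% names(catalog)) {
    function(ids) catalog$gain[match(ids, catalog$stim_id)]
  } else {
    function(ids) rep(1, length(ids))
  }
  imp_v <- numeric(n_vols); imp_a <- numeric(n_vols)
  sus_v <- numeric(n_vols); sus_a <- numeric(n_vols)
  for (r in seq_len(nrow(schedule))) {
    ty <- schedule$trial_type[r]
    sid <- schedule$stim_id[r]
    k0 <- round(schedule$onset[r] / tr) + 1L
    if (ty %in% c("Id-PS", "Mod-PS", "Id-CR-cue")) {
      g <- gain(sid)
      imp_v[k0] <- imp_v[k0] + g * (score(sid, "valence") - 5) / 4
      imp_a[k0] <- imp_a[k0] + g * (score(sid, "arousal") - 5) / 4
    } else if (ty == "Id-CR-recall") {
      ks <- k0 + seq_len(round(schedule$duration[r] / tr)) - 1L
      ks <- ks[ks <= n_vols]
      g <- gain(sid)
      sus_v[ks] <- sus_v[ks] +
        regulation_valence * g * (score(sid, "valence") - 5) / 4
      sus_a[ks] <- sus_a[ks] +
        regulation_arousal * g * (score(sid, "arousal") - 5) / 4
    } else if (ty == "Mod-FS") {
      traj <- if (!is.null(selfinduction)) selfinduction[[as.character(r)]] else NULL
      if (!is.null(traj)) {
        ks <- k0 + seq_along(traj) - 1L
        keep <- ks <= n_vols
        sus_v[ks[keep]] <- sus_v[ks[keep]] + traj[keep]
      }
    }
  }
  list(
    s_v = convolve_hrf(imp_v, tr) + convolve_hrf(sus_v, tr, normalize = TRUE),
    s_a = convolve_hrf(imp_a, tr) + convolve_hrf(sus_a, tr, normalize = TRUE)
  )
}

#' Simulate a preprocessed voxel-by-time series for one scan
#'
#' Implements the linear encoding model underlying the decoders: the
#' signal is `s_v(t) * pattern_valence + s_a(t) * pattern_arousal +
#' drift + noise`, where `s_v` (and analogously `s_a`) is the HRF-convolved
#' train of per-trial impulses with amplitude `(score - 5) / 4` (so Likert
#' extremes map to +/-1). Cued-recall windows add sustained activity at the
#' subject's regulation slope times the cue amplitude; feedback-triggered
#' (Mod-FS) self-induce periods use latent self-induction trajectories
#' (drawn via [simulate_selfinduction()] unless supplied) in place of
#' stimulus impulses. Drift is a per-voxel linear slope drawn
#' `N(0, drift_sd)` per volume; noise is independent Gaussian with the
#' subject's `noise_sd`.
#'
#' @param schedule Events `data.frame` (see [make_id_schedule()]).
#' @param subject A [subject_profile()].
#' @param catalog Stimulus catalog supplying normative scores (optionally a
#'   `gain` column of per-stimulus amplitude multipliers).
#' @param scan_duration Scan length in seconds.
#' @param tr Repetition time in seconds.
#' @param drift_sd SD of the per-voxel linear drift slope, in signal units
#'   per volume (default 0.01). Set to 0 for series that arrive high-pass
#'   filtered.
#' @param selfinduction Optional named list mapping schedule row numbers
#'   (as character) of Mod-FS rows to latent trajectories.
#' @param seed Integer seed.
#' @return A [volume_series()].
#' @export
simulate_volume_series <- function(schedule, subject, catalog,
                                   scan_duration, tr = 2, drift_sd = 0.01,
                                   selfinduction = NULL, seed = NULL) {
  validate_schedule(schedule, tr = tr, scan_duration = scan_duration)
  n_vols <- round(scan_duration / tr)
  if (abs(n_vols * tr - scan_duration) > 1e-9) {
    stop("scan_duration must be an integer number of TRs", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(selfinduction)) {
      fs_rows <- which(schedule$trial_type == "Mod-FS")
      selfinduction <- setNames(lapply(fs_rows, function(r) {
        simulate_selfinduction(subject,
                               duration = min(schedule$duration[r], 38),
                               tr = tr)
      }), as.character(fs_rows))
    }
    amps <- schedule_amplitudes(
      schedule, catalog, n_vols, tr,
      regulation_valence = subject$regulation_slope_valence,
      regulation_arousal = subject$regulation_slope_arousal,
      selfinduction = selfinduction
    )
    p <- length(subject$pattern_valence)
    slopes <- rnorm(p, 0, drift_sd)
    data <- tcrossprod(subject$pattern_valence, amps$s_v) +
      tcrossprod(subject$pattern_arousal, amps$s_a) +
      tcrossprod(slopes, seq_len(n_vols) - 1) +
      matrix(rnorm(p * n_vols, 0, subject$noise_sd), p, n_vols)
    volume_series(data, tr = tr)
  })
}

#' Simulate a resting-state series (no task structure)
#'
#' Noise-only series emulating preprocessed (detrended, high-pass
#' filtered) resting-state data used for surrogate trials.
#'
#' @inheritParams simulate_volume_series
#' @param duration Scan length in seconds (default 450, i.e. 7.5 min).
#' @return A [volume_series()].
#' @export
simulate_rest_series <- function(subject, duration = 450, tr = 2,
                                 drift_sd = 0, seed = NULL) {
  n_vols <- round(duration / tr)
  with_seed(seed, {
    p <- length(subject$pattern_valence)
    data <- matrix(rnorm(p * n_vols, 0, subject$noise_sd), p, n_vols)
    if (drift_sd > 0) {
      data <- data + tcrossprod(rnorm(p, 0, drift_sd), seq_len(n_vols) - 1)
    }
    volume_series(data, tr = tr)
  })
}

#' Latent self-induction trajectory
#'
#' Mean-reverting (AR(1)) process for the volitionally induced valence
#' level during feedback: starts at 0, drifts toward an asymptote of
#' `1.25 * controllability` with Gaussian innovations, clipped to the
#' feedback base range `[-1.25, 1.25]`.
#'
#' @param subject A [subject_profile()]; its `controllability` sets the
#'   asymptote.
#' @param duration Length of the self-induce period in seconds (>= `tr`).
#' @param tr Repetition time in seconds.
#' @param innovation_sd Per-step innovation SD (default 0.15).
#' @param reversion Per-step mean-reversion rate in `(0, 1]` (default
#'   0.25).
#' @param seed Integer seed.
#' @return Numeric vector with one value per volume, bounded in
#'   `[-1.25, 1.25]`.
#' @export
simulate_selfinduction <- function(subject, duration, tr = 2,
                                   innovation_sd = 0.15, reversion = 0.25,
                                   seed = NULL) {
  assert_scalar_number(duration, "duration", lower = tr)
  mu <- 1.25 * subject$controllability
  n <- max(1L, round(duration / tr))
  with_seed(seed, {
    x <- numeric(n)
    level <- 0
    for (k in seq_len(n)) {
      level <- level + reversion * (mu - level) + rnorm(1, 0, innovation_sd)
      level <- min(1.25, max(-1.25, level))
      x[k] <- level
    }
    x
  })
}

#' Simulate trial-level psychophysiological responses
#'
#' Corrugator EMG responds linearly to scaled valence, skin conductance to
#' scaled arousal: `cemg = gain_cemg * (v - 5) / 4 + noise` and
#' `scr = gain_scr * (a - 5) / 4 + noise`. With the default unit noise SD
#' the responses have near-unit variance, so the gains are recovered
#' directly as regression slopes of normative score on the (standardized)
#' response.
#'
#' @param trials Catalog rows (`stim_id`, `valence`, `arousal`) of the
#'   presented stimuli, one row per trial.
#' @param subject A [subject_profile()] supplying the gains.
#' @param noise_sd Response noise SD (default 1).
#' @param seed Integer seed.
#' @return `data.frame` with columns `stim_id`, `cemg`, `scr`.
#' @export
simulate_physio <- function(trials, subject, noise_sd = 1, seed = NULL) {
  with_seed(seed, {
    n <- nrow(trials)
    data.frame(
      stim_id = trials$stim_id,
      cemg = subject$physio_gain_cemg * (trials$valence - 5) / 4 +
        rnorm(n, 0, noise_sd),
      scr = subject$physio_gain_scr * (trials$arousal - 5) / 4 +
        rnorm(n, 0, noise_sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Read / write a volume series as a TSV array container
#'
#' The matrix is stored as plain TSV (voxels x volumes) with a JSON
#' sidecar `<path>.json` holding the `tr` and `t0` attributes.
#'
#' @param series A [volume_series()].
#' @param path File path for the TSV matrix.
#' @return `read_volume_series()` returns the [volume_series()];
#'   `write_volume_series()` returns `path` invisibly.
#' @export
write_volume_series <- function(series, path) {
  stopifnot(inherits(series, "volume_series"))
  write.table(series$data, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(tr = series$tr, t0 = series$t0),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_volume_series
#' @export
read_volume_series <- function(path) {
  data <- as.matrix(read.delim(path, header = FALSE))
  dimnames(data) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"))
  volume_series(data, tr = meta$tr, t0 = meta$t0)
}
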