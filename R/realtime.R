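#' Trigger policy for feedback-triggered stimulus trials
#'
#' Parameters of the closed-loop goal-state criterion: the stimulus is
#' triggered when the (detrended) hyperplane distance stays at or above
#' the threshold for `n_consecutive` volumes; the threshold holds at
#' `threshold0` for `hold` seconds, then decays linearly to 0 over
#' `decay` seconds, at which point the stimulus is triggered by default
#' ("emergency" trigger).
#'
#' @param threshold0 Initial hyperplane-distance threshold (default 0.8).
#' @param n_consecutive Consecutive super-threshold volumes required
#'   (default 4).
#' @param hold Seconds the threshold stays at `threshold0` (default 20).
#' @param decay Seconds of linear decay to 0 (default 18).
#' @param feedback_range Base hyperplane-distance range mapped onto
#'   feedback transparency (default `c(-1.25, 1.25)`).
#' @param detrend_start_index First 1-based volume index (from run start)
#'   at which online detrending is applied (default 40).
#' @param trial_length Fixed Mod-FS trial length in seconds (default 44 =
#'   20 hold + 18 decay + 2 cue + 4 minimum ITI).
#' @param min_iti Minimum inter-trial interval in seconds (default 4).
#' @param cue_duration Stimulus cue duration in seconds (default 2).
#' @return An object of class `trigger_policy`.
#' @export
trigger_policy <- function(threshold0 = 0.8, n_consecutive = 4, hold = 20,
                           decay = 18, feedback_range = c(-1.25, 1.25),
                           detrend_start_index = 40, trial_length = 44,
                           min_iti = 4, cue_duration = 2) {
  assert_scalar_number(threshold0, "threshold0", lower = 1e-12,
                       upper = feedback_range[2])
  assert_scalar_number(n_consecutive, "n_consecutive", lower = 1)
  assert_scalar_number(hold, "hold", lower = 1e-12)
  assert_scalar_number(decay, "decay", lower = 1e-12)
  structure(
    list(threshold0 = threshold0, n_consecutive = as.integer(n_consecutive),
         hold = hold, decay = decay, feedback_range = feedback_range,
         detrend_start_index = as.integer(detrend_start_index),
         trial_length = trial_length, min_iti = min_iti,
         cue_duration = cue_duration),
    class = "trigger_policy"
  )
}

#' Online linear detrending of the hyperplane-distance stream
#'
#' For volume index `i` below `detrend_start_index` the raw value passes
#' through. From `detrend_start_index` on, an ordinary least-squares line
#' is fit to the previous distances `h_1..h_{i-1}` (against their 1-based
#' indices) and its extrapolation at `i` is subtracted from `h_i`.
#'
#' @param history Numeric vector of the previous `i - 1` raw distances.
#' @param h_i Raw hyperplane distance of the current volume.
#' @param i 1-based volume index from run start.
#' @param policy A [trigger_policy()].
#' @return Detrended hyperplane distance.
#' @export
detrend_online <- function(history, h_i, i, policy = trigger_policy()) {
  if (length(history) != i - 1L) {
    stop("history must contain exactly i - 1 values", call. = FALSE)
  }
  if (i < policy$detrend_start_index) return(h_i)
  k <- seq_len(i - 1L)
  kbar <- mean(k)
  hbar <- mean(history)
  m <- sum((k - kbar) * (history - hbar)) / sum((k - kbar)^2)
  c0 <- hbar - m * kbar
  h_i - (m * i + c0)
}

#' Map a hyperplane distance to feedback transparency
#'
#' Affine map of the base range onto `[0, 1]` with clipping: fully
#' transparent (0) at the most negative decodable valence, fully opaque
#' (1) at the most positive. Recomputed once per volume; intra-TR
#' animation smoothing is presentation-only and not modelled.
#'
#' @param h Hyperplane distance (unbounded).
#' @param policy A [trigger_policy()].
#' @return Transparency alpha in `[0, 1]`.
#' @export
feedback_alpha <- function(h, policy = trigger_policy()) {
  lo <- policy$feedback_range[1]
  hi <- policy$feedback_range[2]
  pmin(1, pmax(0, (h - lo) / (hi - lo)))
}

#' Trigger threshold as a function of time within the feedback period
#'
#' @param t Seconds since feedback onset (non-negative, vectorized).
#' @param policy A [trigger_policy()].
#' @return Threshold value(s): `threshold0` during the hold period,
#'   linear decay to 0 over `decay` seconds, 0 afterwards.
#' @export
threshold_at <- function(t, policy = trigger_policy()) {
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  ifelse(t <= policy$hold, policy$threshold0,
         pmax(0, policy$threshold0 * (1 - (t - policy$hold) / policy$decay)))
}

#' Advance the trigger state machine by one volume
#'
#' The consecutive-count increments when the detrended distance meets the
#' time-varying threshold and resets to 0 otherwise; a criterion trigger
#' fires when the count reaches `n_consecutive`, and an emergency trigger
#' fires unconditionally at the first volume at or past the end of the
#' decay if no criterion trigger has occurred.
#'
#' @param state List with elements `consec_count` and `event`
#'   (`NA_character_` before any trigger); use `new_trigger_state()` to
#'   initialize.
#' @param h_detrended Detrended hyperplane distance of this volume.
#' @param t Seconds since feedback onset.
#' @param policy A [trigger_policy()].
#' @return Updated state; `state$event` is `"trigger"`, `"emergency"`, or
#'   `NA_character_`, and `state$threshold_now` records the threshold
#'   evaluated at `t`.
#' @export
step_trigger <- function(state, h_detrended, t, policy = trigger_policy()) {
  if (!is.na(state$event)) {
    stop("step_trigger called after the trial already triggered",
         call. = FALSE)
  }
  thr <- threshold_at(t, policy)
  state$threshold_now <- thr
  if (h_detrended >= thr) {
    state$consec_count <- state$consec_count + 1L
  } else {
    state$consec_count <- 0L
  }
  if (state$consec_count >= policy$n_consecutive) {
    state$event <- "trigger"
  } else if (t >= policy$hold + policy$decay) {
    state$event <- "emergency"
  }
  state
}

#' @rdname step_trigger
#' @export
new_trigger_state <- function() {
  list(consec_count = 0L, event = NA_character_, threshold_now = NA_real_)
}

## incremental HRF convolution value at volume k of impulse train `imp`
## (unit-peak kernel) and sustained train `sus` (unit-sum kernel)
conv_at <- function(imp, sus, k, kern_peak, kern_sum) {
  j <- seq(max(1L, k - length(kern_peak) + 1L), k)
  sum(imp[j] * kern_peak[k - j + 1L]) + sum(sus[j] * kern_sum[k - j + 1L])
}

#' Run one Modulation scan through the closed loop
#'
#' Simulates the run volume-by-volume: latent self-induction drives the
#' planted valence pattern during Mod-FS feedback periods, each simulated
#' volume is decoded with the real-time decoder, the hyperplane distance
#' stream is detrended online, feedback transparency and the trigger state
#' machine are updated per volume, and the pre-assigned stimulus is
#' presented when the trial triggers (one-TR decode delay for criterion
#' triggers; immediate presentation on the emergency default). Passive
#' (Mod-PS) stimuli are presented at their scheduled onsets.
#'
#' @param schedule Modulation-run events table (see [make_mod_schedule()]).
#' @param subject A [subject_profile()].
#' @param catalog Stimulus catalog with normative scores.
#' @param decoder Real-time `decoder_model` (Platt calibration not
#'   required).
#' @param policy A [trigger_policy()].
#' @param scan_duration Scan length in seconds.
#' @param drift_sd Per-voxel drift slope SD (signal units per volume).
#' @param carryover Planted carry-over bias: fraction of the self-induced
#'   level at trigger added to the triggered stimulus' valence amplitude
#'   (default 0; the ground-truth mechanism behind the bias hypothesis).
#' @param seed Integer seed.
#' @return List with `series` (the simulated [volume_series()]), `records`
#'   (one row per Mod-FS trial: trigger time/type, feedback at trigger,
#'   stimulus, congruence, ITI), `trace` (per-volume feedback log over
#'   feedback periods), and `cue_onsets` (named vector of realized Mod-FS
#'   cue onsets).
#' @export
run_modulation_run <- function(schedule, subject, catalog, decoder,
                               policy = trigger_policy(),
                               scan_duration = 630, tr = 2,
                               drift_sd = 0.01, carryover = 0,
                               seed = NULL) {
  validate_schedule(schedule, tr = tr, scan_duration = scan_duration)
  n_vols <- round(scan_duration / tr)
  p <- length(subject$pattern_valence)
  kern_peak <- hrf_kernel(tr)
  kern_sum <- hrf_kernel(tr, normalize = TRUE)
  fs_rows <- which(schedule$trial_type == "Mod-FS")
  with_seed(seed, {
    trajs <- lapply(fs_rows, function(r) {
      simulate_selfinduction(subject, duration = policy$hold + policy$decay,
                             tr = tr)
    })
    names(trajs) <- as.character(fs_rows)
    slopes <- rnorm(p, 0, drift_sd)
    noise <- matrix(rnorm(p * n_vols, 0, subject$noise_sd), p, n_vols)

    imp_v <- numeric(n_vols); imp_a <- numeric(n_vols)
    sus_v <- numeric(n_vols)
    ## scheduled passive stimuli contribute impulses up front
    score <- function(sid, col) catalog[[col]][match(sid, catalog$stim_id)]
    for (r in which(schedule$trial_type == "Mod-PS")) {
      k0 <- round(schedule$onset[r] / tr) + 1L
      sid <- schedule$stim_id[r]
      imp_v[k0] <- imp_v[k0] + (score(sid, "valence") - 5) / 4
      imp_a[k0] <- imp_a[k0] + (score(sid, "arousal") - 5) / 4
    }

    data <- matrix(0, p, n_vols)
    h_raw <- numeric(n_vols)
    trace <- list(); records <- list()
    cue_onsets <- numeric(0)
    ## per-FS-trial bookkeeping
    fs_idx <- if (length(fs_rows)) 1L else NA_integer_
    fs_state <- NULL; fs_onset <- NA_real_; fs_row <- NA_integer_
    fs_level <- 0

    for (k in seq_len(n_vols)) {
      t_k <- (k - 1) * tr
      ## open the next FS trial when its window starts
      if (!is.null(fs_idx) && !is.na(fs_idx) && fs_idx <= length(fs_rows) &&
          is.null(fs_state) && t_k >= schedule$onset[fs_rows[fs_idx]]) {
        fs_row <- fs_rows[fs_idx]
        fs_onset <- schedule$onset[fs_row]
        fs_state <- new_trigger_state()
      }
      in_feedback <- !is.null(fs_state) && is.na(fs_state$event)
      if (in_feedback) {
        traj <- trajs[[as.character(fs_row)]]
        step_i <- floor((t_k - fs_onset) / tr) + 1L
        if (step_i >= 1L && step_i <= length(traj)) {
          sus_v[k] <- sus_v[k] + traj[step_i]
          fs_level <- traj[step_i]
        }
      }
      s_v <- conv_at(imp_v, sus_v, k, kern_peak, kern_sum)
      s_a <- conv_at(imp_a, numeric(n_vols), k, kern_peak, kern_sum)
      data[, k] <- s_v * subject$pattern_valence +
        s_a * subject$pattern_arousal + slopes * (k - 1) + noise[, k]
      h_raw[k] <- hyperplane_distance(decoder, data[, k])
      h_det <- detrend_online(h_raw[seq_len(k - 1L)], h_raw[k], k, policy)

      if (in_feedback) {
        t_fb <- t_k - fs_onset
        fs_state <- step_trigger(fs_state, h_det, t_fb, policy)
        trace[[length(trace) + 1L]] <- data.frame(
          index = k, trial = fs_idx, h_raw = h_raw[k], h_detrended = h_det,
          alpha = feedback_alpha(h_det, policy),
          threshold_now = fs_state$threshold_now,
          consec_count = fs_state$consec_count,
          event = ifelse(is.na(fs_state$event), "none", fs_state$event),
          stringsAsFactors = FALSE)
        if (!is.na(fs_state$event)) {
          sid <- schedule$stim_id[fs_row]
          ## criterion triggers incur a one-TR decode delay; the emergency
          ## default is presented at the emergency volume itself
          cue_t <- if (fs_state$event == "trigger") t_k + tr else t_k
          kc <- round(cue_t / tr) + 1L
          if (kc <= n_vols) {
            imp_v[kc] <- imp_v[kc] + (score(sid, "valence") - 5) / 4 +
              carryover * fs_level
            imp_a[kc] <- imp_a[kc] + (score(sid, "arousal") - 5) / 4
          }
          cue_onsets[sid] <- cue_t
          records[[length(records) + 1L]] <- data.frame(
            trial = fs_idx, stim_id = sid,
            trigger_time = t_fb, trigger_type = fs_state$event,
            feedback_at_trigger = h_det,
            congruence = ifelse(score(sid, "valence") >= 5,
                                "congruent", "incongruent"),
            cue_onset = cue_t,
            iti = fs_onset + policy$trial_length - cue_t -
              policy$cue_duration,
            stringsAsFactors = FALSE)
          fs_state <- NULL
          fs_idx <- fs_idx + 1L
        }
      }
    }
    list(
      series = volume_series(data, tr = tr),
      records = if (length(records)) do.call(rbind, records) else NULL,
      trace = if (length(trace)) do.call(rbind, trace) else NULL,
      cue_onsets = cue_onsets
    )
  })
}

#' Simulate a single feedback-triggered stimulus trial
#'
#' Convenience wrapper running one Mod-FS trial as a miniature run (the
#' trial starting at scan start, so online detrending is in its
#' pass-through regime unless a longer `pad` is used).
#'
#' @param subject A [subject_profile()].
#' @param decoder Real-time `decoder_model`.
#' @param policy A [trigger_policy()].
#' @param stim_id Pre-assigned stimulus to present at trigger.
#' @param catalog Stimulus catalog containing `stim_id`.
#' @param seed Integer seed.
#' @return List with `record` (single-row trial record) and `trace`.
#' @export
run_modfs_trial <- function(subject, decoder, policy = trigger_policy(),
                            stim_id, catalog, tr = 2, seed = NULL) {
  schedule <- data.frame(onset = 0, duration = policy$trial_length,
                         trial_type = "Mod-FS", stim_id = stim_id,
                         stringsAsFactors = FALSE)
  out <- run_modulation_run(schedule, subject, catalog, decoder, policy,
                            scan_duration = policy$trial_length, tr = tr,
                            drift_sd = 0, seed = seed)
  list(record = out$records, trace = out$trace, series = out$series)
}
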