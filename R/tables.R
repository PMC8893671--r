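## Table-level simulation harnesses for parameter recovery and test
## calibration. These generate trial tables directly under the analysis
## models' assumptions (bypassing the fMRI signal chain) so that planted
## coefficients are recovered exactly in expectation; the full signal
## chain is exercised separately by simulate_study().

## cohort-level demographics shared by the harnesses
harness_subjects <- function(n_subjects) {
  data.frame(
    subject_id = sprintf("sub%03d", seq_len(n_subjects)),
    age = round(pmin(65, pmax(20, rnorm(n_subjects, 38.8, 13.3)))),
    sex = sample(c(-0.5, 0.5), n_subjects, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Simulate a Modulation trial table with a planted self-induction bias
#'
#' Generates decoded-valence outcomes under the primary bias model:
#' `y = 0.5 + u_j + delta * I(Mod-FS) + beta_prev * (prev - 0.5) +
#' beta_nv * z(norm valence) + noise`, with the preceding-volume decoding
#' elevated on Mod-FS trials (the self-induced state) and centred at
#' chance on Mod-PS trials. Default variances are calibrated so the
#' fitted model's marginal adjusted R-squared lands near 0.68.
#'
#' @param n_subjects Cohort size (default 40).
#' @param n_ps,n_fs Trials per subject (defaults 40 and 20).
#' @param delta Planted self-induction bias on the probability scale
#'   (default 0.033).
#' @param beta_prev Carry-over coefficient of the preceding volume's
#'   decoding (default 0.803).
#' @param beta_nv Effect of standardized normative valence (default
#'   0.031).
#' @param sigma Residual SD (default 0.08).
#' @param u_sd Subject random-intercept SD (default 0.03).
#' @param seed Integer seed.
#' @return Trial table suitable for [primary_bias_test()].
#' @export
simulate_bias_table <- function(n_subjects = 40, n_ps = 40, n_fs = 20,
                                delta = 0.033, beta_prev = 0.803,
                                beta_nv = 0.031, sigma = 0.08,
                                u_sd = 0.03, seed = NULL) {
  with_seed(seed, {
    subs <- harness_subjects(n_subjects)
    n_trials <- n_ps + n_fs
    rows <- lapply(seq_len(n_subjects), function(j) {
      u <- rnorm(1, 0, u_sd)
      ttype <- sample(rep(c("Mod-PS", "Mod-FS"), c(n_ps, n_fs)))
      is_fs <- ttype == "Mod-FS"
      prev <- ifelse(is_fs, rnorm(n_trials, 0.70, 0.12),
                     rnorm(n_trials, 0.50, 0.12))
      prev <- pmin(0.99, pmax(0.01, prev))
      polarity <- sample(rep(c(1, -1), length.out = n_trials))
      nv <- ifelse(polarity > 0, rnorm(n_trials, 7.38, 0.31),
                   rnorm(n_trials, 2.05, 0.39))
      nv <- pmin(9, pmax(1, nv))
      na <- pmin(9, pmax(1, rnorm(n_trials, 5.7, 0.5)))
      dec_a <- pmin(0.99, pmax(0.01, rnorm(n_trials, 0.5, 0.15)))
      y <- 0.5 + u + delta * is_fs + beta_prev * (prev - 0.5) +
        beta_nv * (nv - mean(nv)) / sd(nv) + rnorm(n_trials, 0, sigma)
      cemg <- rnorm(n_trials, 0, 1)
      scr <- rnorm(n_trials, 0, 1)
      data.frame(
        subject_id = subs$subject_id[j], trial_type = ttype,
        decoded_valence = y, decoded_arousal = dec_a,
        norm_valence = nv, norm_arousal = na,
        prev_decoded_valence = prev, age = subs$age[j], sex = subs$sex[j],
        decoder_accuracy = min(0.95, max(0.3, rnorm(1, 0.55, 0.05))),
        cemg = cemg, scr = scr, stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate a passive-stimulus physiology table with planted gains
#'
#' The planted quantities are the validation models' own regression
#' coefficients (score on standardized response): responses are generated
#' as `response = b_j * (score - mean) / var(score) + noise` with the
#' noise variance completing the response to unit variance, so the
#' population regression coefficient of score on the standardized
#' response equals `b_j` exactly (subject-varying around the planted
#' gain).
#'
#' @param n_subjects,n_trials Cohort and per-subject trial counts
#'   (defaults 39 and 90).
#' @param gain_cemg,gain_scr Population physio gains (defaults 0.11 and
#'   0.07).
#' @param gain_sd Between-subject SD of the gains (default 0.03).
#' @param seed Integer seed.
#' @return Trial table suitable for [physio_validation()].
#' @export
simulate_physio_table <- function(n_subjects = 39, n_trials = 90,
                                  gain_cemg = 0.11, gain_scr = 0.07,
                                  gain_sd = 0.03, seed = NULL) {
  with_seed(seed, {
    subs <- harness_subjects(n_subjects)
    plant <- function(score, b) {
      v <- var(score)
      sigma <- sqrt(max(0.1, 1 - b^2 / v))
      b * (score - mean(score)) / v + rnorm(length(score), 0, sigma)
    }
    rows <- lapply(seq_len(n_subjects), function(j) {
      g_c <- rnorm(1, gain_cemg, gain_sd)
      g_s <- rnorm(1, gain_scr, gain_sd)
      nv <- pmin(9, pmax(1, rnorm(n_trials, 5.04, 1.95)))
      na <- pmin(9, pmax(1, 3.1 + 0.55 * abs(nv - 5) +
                           rnorm(n_trials, 0, 0.9)))
      data.frame(
        subject_id = subs$subject_id[j],
        norm_valence = nv, norm_arousal = na,
        cemg = plant(nv, g_c),
        scr = plant(na, g_s),
        age = subs$age[j], sex = subs$sex[j], stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Simulate a cued-recall regulation table with a planted transfer slope
#'
#' Recall-volume decodings follow
#' `recall = 0.5 + slope_j * (cue - 0.5) + lag_effect * lag + noise`
#' with subject slopes centred on `slope` for task trials and 0 for
#' surrogate trials.
#'
#' @param n_subjects,n_trials Cohort and trials per subject (defaults 39
#'   and 30).
#' @param slope Population regulation slope for task trials (default
#'   0.33).
#' @param slope_sd Between-subject slope SD (default 0.1).
#' @param lag_effect Fixed effect of recall lag (default 0.01).
#' @param sigma Residual SD of recall decodings (default 0.1).
#' @param dimensions Affect dimensions to generate.
#' @param seed Integer seed.
#' @return Long table suitable for [regulation_test()].
#' @export
simulate_regulation_table <- function(n_subjects = 39, n_trials = 30,
                                      slope = 0.33, slope_sd = 0.1,
                                      lag_effect = 0.01, sigma = 0.1,
                                      dimensions = c("valence", "arousal"),
                                      seed = NULL) {
  with_seed(seed, {
    subs <- harness_subjects(n_subjects)
    grid <- expand.grid(dimension = dimensions,
                        source = c("task", "surrogate"),
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(n_subjects), function(j) {
      do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
        s_j <- if (grid$source[g] == "task") rnorm(1, slope, slope_sd) else 0
        cue <- pmin(0.99, pmax(0.01, rnorm(n_trials, 0.5, 0.15)))
        long <- expand.grid(trial = seq_len(n_trials), recall_lag = 1:4)
        long$cue_value <- cue[long$trial]
        long$recall_value <- 0.5 + s_j * (long$cue_value - 0.5) +
          lag_effect * long$recall_lag + rnorm(nrow(long), 0, sigma)
        data.frame(
          subject_id = subs$subject_id[j], dimension = grid$dimension[g],
          source = grid$source[g], cue_value = long$cue_value,
          recall_value = long$recall_value, recall_lag = long$recall_lag,
          age = subs$age[j], sex = subs$sex[j], stringsAsFactors = FALSE
        )
      }))
    })
    do.call(rbind, rows)
  })
}

#' Simulate an induction-predictor table with planted arousal-slope
#' coupling
#'
#' Final self-induce decoded valence is generated as
#' `0.5 + gamma * (aro_slope_j - 0.33) + noise`, so subjects whose
#' unguided arousal regulation is stronger self-induce higher valence.
#'
#' @param n_subjects,n_fs Cohort size and Mod-FS trials per subject.
#' @param gamma Coupling from arousal regulation slope to self-induced
#'   valence (default 0.5; 0 removes the association).
#' @param sigma Residual SD (default 0.1).
#' @param seed Integer seed.
#' @return Table suitable for [induction_predictor_test()].
#' @export
simulate_induction_table <- function(n_subjects = 40, n_fs = 20,
                                     gamma = 0.5, sigma = 0.1,
                                     seed = NULL) {
  with_seed(seed, {
    subs <- harness_subjects(n_subjects)
    rows <- lapply(seq_len(n_subjects), function(j) {
      vs <- rnorm(1, 0.33, 0.12); vi <- rnorm(1, 0.5, 0.05)
      as_ <- rnorm(1, 0.33, 0.12); ai <- rnorm(1, 0.5, 0.05)
      data.frame(
        subject_id = subs$subject_id[j],
        final_valence = 0.5 + gamma * (as_ - 0.33) +
          rnorm(n_fs, 0, sigma),
        val_slope = vs, val_intercept = vi,
        aro_slope = as_, aro_intercept = ai,
        age = subs$age[j], sex = subs$sex[j],
        decoder_accuracy = min(0.95, max(0.3, rnorm(1, 0.55, 0.05))),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
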