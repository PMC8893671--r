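#' Create a synthetic subject profile with planted neural encodings
#'
#' A subject is defined by two unit-norm voxel patterns (the planted
#' encodings of valence and arousal), a per-voxel noise level, a
#' controllability gain in `[0, 1]` governing self-induction skill (the
#' synthetic analogue of BCI literacy), psychophysiological response gains,
#' and demographics. Patterns are random directions re-drawn until their
#' absolute cosine falls below 0.95 (in realistic voxel counts they are
#' near-orthogonal on the first draw).
#'
#' @param subject_id Identifier string.
#' @param n_voxels Number of voxels (default 2000).
#' @param noise_sd Gaussian voxel noise SD in percent-signal-change units
#'   (default 1).
#' @param controllability Self-induction gain in `[0, 1]`.
#' @param physio_gain_cemg Corrugator EMG response units per unit of scaled
#'   valence (default 0.11).
#' @param physio_gain_scr Skin-conductance response units per unit of
#'   scaled arousal (default 0.07).
#' @param age Age in years.
#' @param sex Binary code, `+0.5` (female) or `-0.5` (male).
#' @param regulation_slope_valence,regulation_slope_arousal Unguided
#'   cued-recall regulation gains: the fraction of the cue-evoked response
#'   reinstated during recall.
#' @param seed Integer seed.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id,
                            n_voxels = 2000,
                            noise_sd = 1,
                            controllability = 0.5,
                            physio_gain_cemg = 0.11,
                            physio_gain_scr = 0.07,
                            age = 38.8,
                            sex = 0.5,
                            regulation_slope_valence = 0.33,
                            regulation_slope_arousal = 0.33,
                            seed = NULL) {
  assert_scalar_number(n_voxels, "n_voxels", lower = 2)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(controllability, "controllability", 0, 1)
  with_seed(seed, {
    repeat {
      pv <- rnorm(n_voxels)
      pa <- rnorm(n_voxels)
      pv <- pv / sqrt(sum(pv^2))
      pa <- pa / sqrt(sum(pa^2))
      if (abs(sum(pv * pa)) < 0.95) break
    }
    structure(
      list(
        subject_id = as.character(subject_id),
        pattern_valence = pv,
        pattern_arousal = pa,
        noise_sd = noise_sd,
        controllability = controllability,
        physio_gain_cemg = physio_gain_cemg,
        physio_gain_scr = physio_gain_scr,
        age = age,
        sex = sex,
        regulation_slope_valence = regulation_slope_valence,
        regulation_slope_arousal = regulation_slope_arousal
      ),
      class = "subject_profile"
    )
  })
}

#' @exportS3Method base::print
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile %s: %d voxels, noise_sd=%.3g, controllability=%.2f>\n",
    x$subject_id, length(x$pattern_valence), x$noise_sd, x$controllability
  ))
  invisible(x)
}

#' Draw a cohort of synthetic subjects
#'
#' Controllability varies across subjects (Beta(2, 2), spanning poor to
#' good self-inducers) and is positively coupled to the subject's unguided
#' arousal-regulation slope, so that unguided regulation ability predicts
#' guided self-induction downstream.
#'
#' @param n_subjects Cohort size.
#' @param n_voxels Voxels per subject.
#' @param noise_sd Voxel noise SD shared by the cohort.
#' @param coupling Gain from (centred) arousal-regulation slope to
#'   controllability; 0 removes the planted association.
#' @param seed Integer seed.
#' @return List of `subject_profile` objects.
#' @export
simulate_cohort <- function(n_subjects, n_voxels = 2000, noise_sd = 1,
                            coupling = 1.5, seed = NULL) {
  assert_scalar_number(n_subjects, "n_subjects", lower = 1)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      reg_a <- pmax(0, rnorm(1, 0.33, 0.12))
      ctrl <- stats::rbeta(1, 2, 2) + coupling * (reg_a - 0.33)
      subject_profile(
        subject_id = sprintf("sub%03d", i),
        n_voxels = n_voxels,
        noise_sd = noise_sd,
        controllability = min(1, max(0, ctrl)),
        age = round(min(65, max(20, rnorm(1, 38.8, 13.3)))),
        sex = sample(c(-0.5, 0.5), 1),
        regulation_slope_valence = pmax(0, rnorm(1, 0.33, 0.12)),
        regulation_slope_arousal = reg_a,
        seed = NULL
      )
    })
  })
}
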