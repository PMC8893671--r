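## Results-stage statistical analyses. All continuous covariates are
## z-scored before fitting (sex is coded +/-0.5), so reported effects are
## on the standardized-covariate scale while outcomes stay on their native
## scale (Likert scores or decoded probabilities).

std_cols <- function(table, cols) {
  for (cl in intersect(cols, names(table))) table[[cl]] <- zscore(table[[cl]])
  table
}

#' Psychophysiological validation of stimulus-induced affect
#'
#' Models normative valence from corrugator EMG and normative arousal from
#' skin conductance (subject-wise random slopes and intercepts,
#' controlling for age and sex), plus the crossed selectivity models
#' (cEMG predicting arousal, SCR predicting valence).
#'
#' @param table Passive-stimulus trial rows with columns `subject_id`,
#'   `norm_valence`, `norm_arousal`, `cemg`, `scr`, `age`, `sex`.
#' @return List of four `affect_fit`s: `valence_cemg`, `arousal_scr`,
#'   `arousal_cemg`, `valence_scr`.
#' @export
physio_validation <- function(table) {
  table <- std_cols(table, c("cemg", "scr", "age"))
  list(
    valence_cemg = fit_mixed(
      norm_valence ~ cemg + age + sex + (1 + cemg | subject_id), table),
    arousal_scr = fit_mixed(
      norm_arousal ~ scr + age + sex + (1 + scr | subject_id), table),
    arousal_cemg = fit_mixed(
      norm_arousal ~ cemg + age + sex + (1 + cemg | subject_id), table),
    valence_scr = fit_mixed(
      norm_valence ~ scr + age + sex + (1 + scr | subject_id), table)
  )
}

#' Validation of decoder generalization to novel stimuli
#'
#' Cued-recall cue stimuli: normative score modeled from the
#' same-dimension decoding (subject-wise random slopes). Modulation
#' passive stimuli: additionally controls for the decoding of the
#' complementary affect dimension (the polar stimulus sampling makes this
#' a necessary covariate).
#'
#' @param idcr_table,modps_table Trial rows with columns `subject_id`,
#'   `norm_valence`, `norm_arousal`, `decoded_valence`, `decoded_arousal`,
#'   `age`, `sex`.
#' @return List of `affect_fit`s: `idcr_valence`, `idcr_arousal`,
#'   `modps_valence`, `modps_arousal`.
#' @export
novel_stimulus_validation <- function(idcr_table, modps_table) {
  idcr <- std_cols(idcr_table, c("decoded_valence", "decoded_arousal", "age"))
  modps <- std_cols(modps_table, c("decoded_valence", "decoded_arousal", "age"))
  list(
    idcr_valence = fit_mixed(
      norm_valence ~ decoded_valence + age + sex +
        (1 + decoded_valence | subject_id), idcr),
    idcr_arousal = fit_mixed(
      norm_arousal ~ decoded_arousal + age + sex +
        (1 + decoded_arousal | subject_id), idcr),
    modps_valence = fit_mixed(
      norm_valence ~ decoded_valence + decoded_arousal + age + sex +
        (1 + decoded_valence | subject_id), modps),
    modps_arousal = fit_mixed(
      norm_arousal ~ decoded_arousal + decoded_valence + age + sex +
        (1 + decoded_arousal | subject_id), modps)
  )
}

#' Validation of the real-time trigger state
#'
#' (a) One-sided signed-rank test that the median feedback signal at the
#' moment of stimulus trigger exceeds 0. (b) One-sided bootstrap
#' (within-subject resampling before pooling) that the mean post-hoc
#' decoded valence of the trigger volume exceeds chance 0.5, restricted
#' to subjects with significant within-subject valence decoding.
#'
#' @param records Mod-FS trial records: columns `subject_id`,
#'   `feedback_at_trigger`.
#' @param table Mod-FS rows: columns `subject_id`,
#'   `trigger_decoded_valence`, `accuracy_p` (within-subject binomial p).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param alpha Qualification level for within-subject decoding
#'   (default 0.05).
#' @param seed Integer seed for the bootstrap.
#' @return List with `median_feedback`, `median_p`, `boot_mean`,
#'   `boot_p`, `n_qualifying`.
#' @export
trigger_validation <- function(records, table, n_boot = 10000,
                               alpha = 0.05, seed = NULL) {
  if (!nrow(records)) stop("no Mod-FS records", call. = FALSE)
  sr <- suppressWarnings(
    wilcox.test(records$feedback_at_trigger, mu = 0,
                alternative = "greater", exact = FALSE)
  )
  qual <- table[table$accuracy_p < alpha, ]
  if (!nrow(qual)) {
    stop("no subjects with significant within-subject decoding",
         call. = FALSE)
  }
  split_vals <- split(qual$trigger_decoded_valence, qual$subject_id)
  split_vals <- split_vals[vapply(split_vals, length, integer(1)) > 0]
  boot_means <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      mean(unlist(lapply(split_vals, function(v) {
        v[sample.int(length(v), length(v), replace = TRUE)]
      })))
    }, numeric(1))
  })
  list(
    median_feedback = median(records$feedback_at_trigger),
    median_p = sr$p.value,
    boot_mean = mean(unlist(split_vals)),
    boot_p = mean(boot_means <= 0.5),
    n_qualifying = length(split_vals)
  )
}

#' Primary hypothesis test: self-induction bias of subsequent decoding
#'
#' Outcome (decoded valence of the test stimulus, or a
#' psychophysiological response) modeled from trial type (feedback- vs
#' randomly-triggered), normative valence, decoded arousal, age, sex,
#' within-subject decoder accuracy, and the decoded valence of the volume
#' immediately preceding the stimulus, with trial-type interactions with
#' normative valence and the preceding decoding; subject-wise random
#' intercepts. The `trial_typeMod-FS` coefficient is the self-induction
#' bias on the outcome scale.
#'
#' @param table Modulation trial rows: columns `subject_id`, `trial_type`
#'   (`"Mod-PS"`/`"Mod-FS"`), `decoded_valence`, `decoded_arousal`,
#'   `norm_valence`, `norm_arousal`, `prev_decoded_valence`, `age`, `sex`,
#'   `decoder_accuracy` (plus `cemg`/`scr` for the physio variants).
#' @param outcome Response column (default `"decoded_valence"`).
#' @return An `affect_fit`.
#' @export
primary_bias_test <- function(table, outcome = "decoded_valence") {
  stopifnot(all(c("Mod-PS", "Mod-FS") %in% table$trial_type))
  table$trial_type <- stats::relevel(factor(table$trial_type), "Mod-PS")
  table <- std_cols(table, c("norm_valence", "norm_arousal",
                             "decoded_arousal", "age", "decoder_accuracy",
                             "prev_decoded_valence"))
  fml <- as.formula(paste(
    outcome, "~ trial_type + norm_valence + decoded_arousal + age + sex +",
    "decoder_accuracy + prev_decoded_valence + trial_type:norm_valence +",
    "trial_type:prev_decoded_valence + (1 | subject_id)"
  ))
  fit_mixed(fml, table)
}

#' Cued-recall affect regulation with surrogate comparison
#'
#' Models the decoded affect of the four recall volumes from the decoded
#' cue affect (the regulation goal) plus recall lag, age and sex, with
#' subject-wise random slopes and intercepts; fits the identical model to
#' surrogate resting-state trials; and compares per-subject regulation
#' slopes (task minus surrogate) with a one-sided signed-rank test.
#'
#' @param table Long recall rows: columns `subject_id`, `dimension`
#'   (`"valence"`/`"arousal"`), `source` (`"task"`/`"surrogate"`),
#'   `cue_value`, `recall_value`, `recall_lag`, `age`, `sex`.
#' @return List with per-dimension `affect_fit`s (`valence`, `arousal`,
#'   `surrogate_valence`, `surrogate_arousal`), a `slopes` data.frame of
#'   per-subject slopes and intercepts, and signed-rank p-values
#'   `comparison_p_valence`, `comparison_p_arousal`.
#' @export
regulation_test <- function(table) {
  table <- std_cols(table, "age")
  fit_one <- function(dim, src) {
    rows <- table[table$dimension == dim & table$source == src, ]
    fit_mixed(recall_value ~ cue_value + recall_lag + age + sex +
                (1 + cue_value | subject_id), rows)
  }
  fits <- list(
    valence = fit_one("valence", "task"),
    arousal = fit_one("arousal", "task"),
    surrogate_valence = fit_one("valence", "surrogate"),
    surrogate_arousal = fit_one("arousal", "surrogate")
  )
  ## per-subject slopes/intercepts by unpooled OLS: mixed-model subject
  ## effects shrink to a common value when the random-slope variance is
  ## estimated at zero, which would degenerate downstream predictors
  subj_coefs <- function(dim, src) {
    rows <- table[table$dimension == dim & table$source == src, ]
    out <- lapply(split(rows, rows$subject_id), function(d) {
      coef(lm(recall_value ~ cue_value + recall_lag, data = d))
    })
    data.frame(subject_id = names(out),
               slope = vapply(out, `[[`, numeric(1), "cue_value"),
               intercept = vapply(out, `[[`, numeric(1), "(Intercept)"),
               stringsAsFactors = FALSE)
  }
  slopes <- Reduce(function(a, b) merge(a, b, by = "subject_id"), list(
    setNames(subj_coefs("valence", "task"),
             c("subject_id", "val_slope", "val_intercept")),
    setNames(subj_coefs("arousal", "task"),
             c("subject_id", "aro_slope", "aro_intercept")),
    setNames(subj_coefs("valence", "surrogate"),
             c("subject_id", "val_slope_surr", "val_intercept_surr")),
    setNames(subj_coefs("arousal", "surrogate"),
             c("subject_id", "aro_slope_surr", "aro_intercept_surr"))
  ))
  cmp <- function(a, b) {
    suppressWarnings(
      wilcox.test(a, b, paired = TRUE, alternative = "greater",
                  exact = FALSE)$p.value
    )
  }
  fits$slopes <- slopes
  fits$comparison_p_valence <- cmp(slopes$val_slope, slopes$val_slope_surr)
  fits$comparison_p_arousal <- cmp(slopes$aro_slope, slopes$aro_slope_surr)
  fits
}

#' Unguided regulation ability as a predictor of guided self-induction
#'
#' Models the decoded valence of the final self-induce volume of Mod-FS
#' trials from the subject's unguided regulation parameters (valence and
#' arousal slopes and intercepts from [regulation_test()]), age, sex, and
#' decoder accuracy, with all slope/intercept pairwise interactions and
#' valence slope/intercept interactions with age, sex, and accuracy;
#' subject-wise random intercepts.
#'
#' @param table Mod-FS rows: columns `subject_id`, `final_valence`,
#'   `val_slope`, `val_intercept`, `aro_slope`, `aro_intercept`, `age`,
#'   `sex`, `decoder_accuracy`.
#' @param terms Fixed-effect structure: `"full"` (default) includes all
#'   slope/intercept pairwise interactions plus valence slope/intercept
#'   interactions with age, sex and accuracy (19 fixed effects — all
#'   subject-level, so the cohort must be comfortably larger than that);
#'   `"main"` keeps main effects only; `"minimal"` regresses on the
#'   regulation slopes alone (tiny cohorts).
#' @return An `affect_fit`.
#' @export
induction_predictor_test <- function(table,
                                     terms = c("full", "main", "minimal")) {
  terms <- match.arg(terms)
  table <- std_cols(table, c("val_slope", "val_intercept", "aro_slope",
                             "aro_intercept", "age", "decoder_accuracy"))
  fml <- switch(
    terms,
    full = final_valence ~
      (val_slope + val_intercept + aro_slope + aro_intercept)^2 +
      age + sex + decoder_accuracy +
      val_slope:age + val_slope:sex + val_slope:decoder_accuracy +
      val_intercept:age + val_intercept:sex +
      val_intercept:decoder_accuracy + (1 | subject_id),
    main = final_valence ~ val_slope + val_intercept + aro_slope +
      aro_intercept + age + sex + decoder_accuracy + (1 | subject_id),
    minimal = final_valence ~ val_slope + aro_slope + (1 | subject_id)
  )
  X <- model.matrix(lme4::nobars(fml), table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)),
                                   qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit_mixed(fml, table)
}
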