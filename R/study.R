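#' Remove per-voxel linear trends from a volume series
#'
#' Ordinary least-squares detrending against volume index, retaining the
#' voxel mean (the batch analogue of the preprocessing applied before
#' decoding).
#'
#' @param series A [volume_series()].
#' @return A detrended [volume_series()].
#' @export
detrend_series <- function(series) {
  stopifnot(inherits(series, "volume_series"))
  n <- ncol(series$data)
  k <- seq_len(n) - (n + 1) / 2 # centred index
  denom <- sum(k^2)
  slopes <- drop(series$data %*% k) / denom
  series$data <- series$data - tcrossprod(slopes, k)
  series
}

## decoder training label from a normative score (middle Likert boundary)
score_label <- function(score) {
  lab <- sign(score - 5)
  as.integer(lab)
}

#' Simulate a complete closed-loop affect-decoding study
#'
#' Runs the full synthetic pipeline for a cohort: stimulus catalog
#' generation and selection (maximal-span Identification sets, polar
#' arousal-matched Modulation sets), per-subject Identification scans,
#' real-time and post-hoc decoder training with Platt calibration and
#' cross-validated accuracy, closed-loop Modulation scans through the
#' trigger state machine, resting-state surrogate trials, trial-level
#' psychophysiology, and assembly of all analysis tables.
#'
#' @param n_subjects Cohort size (default 8; the study design used 40).
#' @param n_voxels Voxels per subject (default 300; with independent voxel
#'   noise this compact-ROI scale reproduces the modest full-set decoding
#'   accuracy regime of affect decoders, which larger counts cannot).
#' @param noise_sd Voxel noise SD (default 0.6).
#' @param catalog_n Catalog size (default 500).
#' @param carryover Planted self-induction carry-over amplitude (default
#'   0.2; see [run_modulation_run()]).
#' @param theta Volume-labelling threshold (default 0.2).
#' @param tr Repetition time, seconds.
#' @param seed Integer seed driving all randomness.
#' @return A `study` list: `catalog`, `assignment`, `polar`, `policy`,
#'   `cohort`, per-subject `decoders`, `beta_mats`/`beta_labels` (for
#'   encoding analyses), `reliable_set`, and analysis `tables`
#'   (`physio`, `idcr`, `bias`, `regulation`, `records`).
#' @export
simulate_study <- function(n_subjects = 8, n_voxels = 300, noise_sd = 0.6,
                           catalog_n = 500, carryover = 0.2, theta = 0.2,
                           tr = 2, seed = NULL) {
  ## arousal matching can collapse by chance on a given catalog (the
  ## rank-sum test is significant at its alpha rate even for matched
  ## pools), so regenerate the catalog on infeasibility, bounded retries
  for (try in 0:9) {
    catalog <- generate_stimulus_catalog(catalog_n,
                                         seed = child_seed(seed, 1 + 10 * try))
    ## heterogeneous per-stimulus pattern strength (drives the
    ## reliable-set accuracy ordering)
    catalog$gain <- with_seed(child_seed(seed, 2 + 10 * try),
                              runif(catalog_n, 0.4, 1.6))
    id_ps <- maxspan_sample(catalog, 90, seed = child_seed(seed, 3))
    id_cr <- maxspan_sample(catalog[!catalog$stim_id %in% id_ps, ], 30,
                            seed = child_seed(seed, 4))
    polar <- tryCatch(
      polar_subsets(catalog[!catalog$stim_id %in% c(id_ps, id_cr), ],
                    n_per_side = 30, seed = child_seed(seed, 5)),
      error = function(e) NULL
    )
    if (!is.null(polar)) break
  }
  if (is.null(polar)) {
    stop("could not build arousal-matched polar subsets after 10 catalogs",
         call. = FALSE)
  }
  assignment <- assign_trials(polar, n_ps = 40, n_fs = 20,
                              seed = child_seed(seed, 6))
  policy <- trigger_policy()

  ## trial orders are fixed across subjects
  sched_id <- make_id_schedule(id_ps, id_cr, tr = tr,
                               seed = child_seed(seed, 7))
  sched_mod <- make_mod_schedule(
    assignment$stim_id[assignment$trial_type == "Mod-PS"],
    assignment$stim_id[assignment$trial_type == "Mod-FS"],
    tr = tr, fs_length = policy$trial_length, seed = child_seed(seed, 8)
  )
  cohort <- simulate_cohort(n_subjects, n_voxels = n_voxels,
                            noise_sd = noise_sd,
                            seed = child_seed(seed, 9))

  subjects <- lapply(seq_len(n_subjects), function(j) {
    simulate_study_subject(cohort[[j]], catalog, sched_id, sched_mod,
                           policy, theta = theta, tr = tr,
                           carryover = carryover,
                           seed = child_seed(seed, 100 + j))
  })

  ## reliable stimulus set across subjects, and per-subject accuracy on it;
  ## within-subject significance (used to qualify subjects for the trigger
  ## bootstrap) is assessed on the reliable set
  beta_series_list <- lapply(subjects, function(s) {
    structure(list(beta = t(s$idps_features)), class = "beta_series")
  })
  reliable <- if (length(subjects) >= 2L) {
    reliable_stimulus_set(beta_series_list, fraction = 0.5)
  } else {
    ## inter-subject reliability is undefined for one subject
    rownames(subjects[[1]]$idps_features)
  }
  acc <- do.call(rbind, lapply(seq_along(subjects), function(j) {
    s <- subjects[[j]]
    rel_idx <- rownames(s$idps_features) %in% reliable
    k_rel <- sum(sign(s$cv_valence$h[rel_idx]) == s$valence_labels[rel_idx])
    n_rel <- sum(rel_idx)
    data.frame(
      subject_id = cohort[[j]]$subject_id,
      decoder_accuracy = s$cv_valence$accuracy,
      accuracy_reliable = k_rel / n_rel,
      accuracy_p = pbinom(k_rel - 1, n_rel, 0.5, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }))
  decoders <- lapply(seq_along(subjects), function(j) {
    d <- subjects[[j]]$decoders
    d$valence$accuracy_full <- acc$decoder_accuracy[j]
    d$valence$accuracy_reliable <- acc$accuracy_reliable[j]
    d
  })

  tables <- assemble_tables(subjects, cohort, acc)
  list(
    catalog = catalog, assignment = assignment, polar = polar,
    policy = policy, cohort = cohort, decoders = decoders,
    beta_mats = lapply(subjects, `[[`, "idps_features"),
    beta_labels = lapply(subjects, `[[`, "valence_labels"),
    reliable_set = reliable,
    tables = tables
  )
}

## one subject's full acquisition + decoding; internal to simulate_study
simulate_study_subject <- function(subject, catalog, sched_id, sched_mod,
                                   policy, theta = 0.2, tr = 2,
                                   carryover = 0.2, seed = NULL) {
  id_dur <- 564; mod_dur <- 630
  feats_rt <- list(); labs_rt <- list()
  beta_all <- list()
  for (r in seq_along(sched_id)) {
    series <- simulate_volume_series(sched_id[[r]], subject, catalog,
                                     scan_duration = id_dur, tr = tr,
                                     seed = child_seed(seed, 10 + r))
    series <- detrend_series(series)
    ps_rows <- sched_id[[r]]$trial_type == "Id-PS"
    reg <- build_class_regressor(
      sched_id[[r]]$onset[ps_rows],
      catalog$valence[match(sched_id[[r]]$stim_id[ps_rows],
                            catalog$stim_id)],
      tr, ncol(series$data)
    )
    feats_rt[[r]] <- t(series$data)
    labs_rt[[r]] <- label_volumes(reg, theta = theta)
    ev <- events_from_schedule(
      sched_id[[r]], types = c("Id-PS", "Id-CR-cue", "Id-CR-recall"),
      tr = tr
    )
    beta_all[[r]] <- extract_beta_series(series, ev)
  }
  rt_decoder <- train_linear_classifier(do.call(rbind, feats_rt),
                                        unlist(labs_rt),
                                        dimension = "valence")
  beta <- do.call(cbind, lapply(beta_all, `[[`, "beta"))

  id_ps_tags <- unlist(lapply(sched_id, function(s) {
    s$stim_id[s$trial_type == "Id-PS"]
  }))
  idps_features <- t(beta[, id_ps_tags, drop = FALSE])
  v_scores <- catalog$valence[match(id_ps_tags, catalog$stim_id)]
  a_scores <- catalog$arousal[match(id_ps_tags, catalog$stim_id)]
  v_labels <- score_label(v_scores)
  a_labels <- score_label(a_scores)

  ## Platt coefficients are fit on cross-validated decision values: the
  ## full model's training margins are separable in this regime and would
  ## saturate the calibrated probabilities
  dec_v <- train_linear_classifier(idps_features, v_labels,
                                   dimension = "valence")
  cv_v <- cv_accuracy(idps_features, v_labels, k = 10,
                      seed = child_seed(seed, 20))
  ab <- fit_platt(cv_v$h, v_labels)
  dec_v$platt_a <- unname(ab["platt_a"]); dec_v$platt_b <- unname(ab["platt_b"])
  dec_a <- train_linear_classifier(idps_features, a_labels,
                                   dimension = "arousal")
  cv_a <- cv_accuracy(idps_features, a_labels, k = 10,
                      seed = child_seed(seed, 21))
  ab <- fit_platt(cv_a$h, a_labels)
  dec_a$platt_a <- unname(ab["platt_a"]); dec_a$platt_b <- unname(ab["platt_b"])

  ## Id-CR decodings (cue + 4 recall volumes)
  cr_tags <- unlist(lapply(sched_id, function(s) {
    s$stim_id[s$trial_type == "Id-CR-cue"]
  }))
  idcr <- data.frame(
    stim_id = cr_tags,
    norm_valence = catalog$valence[match(cr_tags, catalog$stim_id)],
    norm_arousal = catalog$arousal[match(cr_tags, catalog$stim_id)],
    decoded_valence = decode(dec_v, t(beta[, cr_tags, drop = FALSE])),
    decoded_arousal = decode(dec_a, t(beta[, cr_tags, drop = FALSE])),
    stringsAsFactors = FALSE
  )
  recall_rows <- do.call(rbind, lapply(cr_tags, function(s) {
    tags <- sprintf("%s:recall%d", s, 1:4)
    data.frame(
      stim_id = s, recall_lag = 1:4,
      recall_valence = decode(dec_v, t(beta[, tags, drop = FALSE])),
      recall_arousal = decode(dec_a, t(beta[, tags, drop = FALSE])),
      stringsAsFactors = FALSE
    )
  }))

  ## Modulation runs through the closed loop
  records <- list(); mod_rows <- list()
  for (r in seq_along(sched_mod)) {
    loop <- run_modulation_run(sched_mod[[r]], subject, catalog, rt_decoder,
                               policy, scan_duration = mod_dur, tr = tr,
                               carryover = carryover,
                               seed = child_seed(seed, 30 + r))
    series <- detrend_series(loop$series)
    ev <- events_from_schedule(sched_mod[[r]], types = c("Mod-PS", "Mod-FS"),
                               pre_cue = TRUE, tr = tr,
                               cue_onsets = loop$cue_onsets)
    bs <- extract_beta_series(series, ev)
    cue_ev <- ev[!grepl(":pre$", ev$tag), ]
    pre_tag <- paste0(cue_ev$stim_id, ":pre")
    has_pre <- pre_tag %in% ev$tag
    mod_rows[[r]] <- data.frame(
      stim_id = cue_ev$stim_id,
      trial_type = cue_ev$trial_type,
      decoded_valence = decode(dec_v, t(bs$beta[, cue_ev$tag, drop = FALSE])),
      decoded_arousal = decode(dec_a, t(bs$beta[, cue_ev$tag, drop = FALSE])),
      prev_decoded_valence = ifelse(
        has_pre,
        decode(dec_v, t(bs$beta[, ifelse(has_pre, pre_tag, cue_ev$tag),
                                drop = FALSE])),
        NA_real_),
      norm_valence = catalog$valence[match(cue_ev$stim_id, catalog$stim_id)],
      norm_arousal = catalog$arousal[match(cue_ev$stim_id, catalog$stim_id)],
      stringsAsFactors = FALSE
    )
    records[[r]] <- loop$records
  }
  records <- do.call(rbind, records)
  mod_rows <- do.call(rbind, mod_rows)

  ## resting state and surrogate trials (same onsets for both dimensions)
  rest <- simulate_rest_series(subject, duration = 450, tr = tr,
                               seed = child_seed(seed, 40))
  surro_seed <- child_seed(seed, 41)
  surro_v <- sample_surrogate_trials(decode_resting(rest, dec_v), n = 30,
                                     tr = tr, seed = surro_seed)
  surro_a <- sample_surrogate_trials(decode_resting(rest, dec_a), n = 30,
                                     tr = tr, seed = surro_seed)

  ## trial-level psychophysiology for passive-stimulus trials
  physio_id <- simulate_physio(
    catalog[match(id_ps_tags, catalog$stim_id), ], subject,
    seed = child_seed(seed, 50))
  physio_mod <- simulate_physio(
    catalog[match(mod_rows$stim_id, catalog$stim_id), ], subject,
    seed = child_seed(seed, 51))

  list(
    subject = subject,
    decoders = list(valence = dec_v, arousal = dec_a, realtime = rt_decoder),
    idps_features = idps_features,
    valence_labels = v_labels, arousal_labels = a_labels,
    cv_valence = cv_v, cv_arousal = cv_a,
    idcr = idcr, recall = recall_rows,
    mod = cbind(mod_rows, physio_mod[, c("cemg", "scr")]),
    records = records,
    surrogate = list(valence = surro_v, arousal = surro_a),
    physio_id = cbind(
      physio_id,
      norm_valence = catalog$valence[match(id_ps_tags, catalog$stim_id)],
      norm_arousal = catalog$arousal[match(id_ps_tags, catalog$stim_id)]
    )
  )
}

## combine per-subject outputs into the long analysis tables
assemble_tables <- function(subjects, cohort, acc) {
  demo <- function(j) {
    data.frame(subject_id = cohort[[j]]$subject_id, age = cohort[[j]]$age,
               sex = cohort[[j]]$sex, stringsAsFactors = FALSE)
  }
  bind <- function(field, extra = NULL) {
    do.call(rbind, lapply(seq_along(subjects), function(j) {
      x <- subjects[[j]][[field]]
      if (is.null(x) || !nrow(x)) return(NULL)
      cbind(x, demo(j), row.names = NULL)
    }))
  }
  physio <- bind("physio_id")
  idcr <- bind("idcr")
  mod <- bind("mod")
  records <- bind("records")
  mod <- merge(mod, acc, by = "subject_id")
  mod$trigger_decoded_valence <- ifelse(mod$trial_type == "Mod-FS",
                                        mod$prev_decoded_valence, NA_real_)

  regulation <- do.call(rbind, lapply(seq_along(subjects), function(j) {
    s <- subjects[[j]]; d <- demo(j)
    task <- merge(s$recall, s$idcr[, c("stim_id", "decoded_valence",
                                       "decoded_arousal")], by = "stim_id")
    long_task <- rbind(
      data.frame(dimension = "valence", source = "task",
                 cue_value = task$decoded_valence,
                 recall_value = task$recall_valence,
                 recall_lag = task$recall_lag, stringsAsFactors = FALSE),
      data.frame(dimension = "arousal", source = "task",
                 cue_value = task$decoded_arousal,
                 recall_value = task$recall_arousal,
                 recall_lag = task$recall_lag, stringsAsFactors = FALSE)
    )
    long_surr <- rbind(
      data.frame(dimension = "valence", source = "surrogate",
                 cue_value = s$surrogate$valence$cue_value,
                 recall_value = s$surrogate$valence$recall_value,
                 recall_lag = s$surrogate$valence$recall_lag,
                 stringsAsFactors = FALSE),
      data.frame(dimension = "arousal", source = "surrogate",
                 cue_value = s$surrogate$arousal$cue_value,
                 recall_value = s$surrogate$arousal$recall_value,
                 recall_lag = s$surrogate$arousal$recall_lag,
                 stringsAsFactors = FALSE)
    )
    cbind(rbind(long_task, long_surr), d, row.names = NULL)
  }))

  list(physio = physio, idcr = idcr, bias = mod, regulation = regulation,
       records = records)
}

#' Run all Results-stage analyses on a simulated study
#'
#' @param study Output of [simulate_study()].
#' @param n_boot Bootstrap resamples for the trigger validation.
#' @param seed Integer seed for the bootstrap.
#' @return List of analysis results: `physio`, `novel`, `trigger`,
#'   `primary`, `primary_scr`, `primary_cemg`, `regulation`, `induction`.
#' @export
run_study_analyses <- function(study, n_boot = 10000, seed = NULL) {
  tables <- study$tables
  physio <- physio_validation(tables$physio)
  novel <- novel_stimulus_validation(
    tables$idcr, tables$bias[tables$bias$trial_type == "Mod-PS", ])
  fs_rows <- tables$bias[tables$bias$trial_type == "Mod-FS", ]
  trigger <- trigger_validation(tables$records, fs_rows, n_boot = n_boot,
                                seed = child_seed(seed, 1))
  primary <- primary_bias_test(tables$bias)
  primary_scr <- primary_bias_test(tables$bias, outcome = "scr")
  primary_cemg <- primary_bias_test(tables$bias, outcome = "cemg")
  regulation <- regulation_test(tables$regulation)
  ind_table <- merge(
    data.frame(subject_id = fs_rows$subject_id,
               final_valence = fs_rows$prev_decoded_valence,
               age = fs_rows$age, sex = fs_rows$sex,
               decoder_accuracy = fs_rows$decoder_accuracy,
               stringsAsFactors = FALSE),
    regulation$slopes[, c("subject_id", "val_slope", "val_intercept",
                          "aro_slope", "aro_intercept")],
    by = "subject_id"
  )
  n_sub <- length(unique(ind_table$subject_id))
  induction <- induction_predictor_test(
    ind_table,
    terms = if (n_sub >= 24) "full" else if (n_sub >= 12) "main" else "minimal")
  list(physio = physio, novel = novel, trigger = trigger,
       primary = primary, primary_scr = primary_scr,
       primary_cemg = primary_cemg, regulation = regulation,
       induction = induction)
}
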