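test_that("physio validation recovers planted gains and is selective", {
  tab <- simulate_physio_table(n_subjects = 39, n_trials = 90, seed = 61)
  fits <- physio_validation(tab)
  cemg <- fits$valence_cemg$fixed_effects
  row <- cemg[cemg$term == "cemg", ]
  expect_lt(abs(row$estimate - 0.11), 1.96 * row$se)
  expect_lt(row$p, 0.05)
  scr <- fits$arousal_scr$fixed_effects
  row_s <- scr[scr$term == "scr", ]
  expect_lt(abs(row_s$estimate - 0.07), 1.96 * row_s$se)
  ## crossed models: cEMG planted on valence only is not an arousal
  ## predictor beyond the valence-arousal coupling of the stimulus set;
  ## a zero-gain world is null everywhere
  null_tab <- simulate_physio_table(gain_cemg = 0, gain_scr = 0, seed = 62)
  null_fits <- physio_validation(null_tab)
  for (f in null_fits) {
    expect_gt(f$fixed_effects$p[2], 0.05)
  }
})

test_that("novel-stimulus validation detects planted decodability", {
  withr::with_seed(63, {
    n_sub <- 20; n_tr <- 30
    mk <- function(link) {
      do.call(rbind, lapply(1:n_sub, function(j) {
        nv <- pmin(9, pmax(1, rnorm(n_tr, 5.3, 1.95)))
        na <- pmin(9, pmax(1, 3.1 + 0.55 * abs(nv - 5) + rnorm(n_tr, 0, 0.9)))
        data.frame(
          subject_id = sprintf("s%02d", j),
          norm_valence = nv, norm_arousal = na,
          decoded_valence = plogis(link * (nv - 5) / 2 + rnorm(n_tr, 0, 1)),
          decoded_arousal = plogis(link * (na - 5) / 2 + rnorm(n_tr, 0, 1)),
          age = 40, sex = sample(c(-0.5, 0.5), 1),
          stringsAsFactors = FALSE
        )
      }))
    }
    linked <- mk(1)
    broken <- mk(1)
    broken$decoded_valence <- sample(broken$decoded_valence)
    broken$decoded_arousal <- sample(broken$decoded_arousal)
  })
  fits <- novel_stimulus_validation(linked, linked)
  for (nm in c("idcr_valence", "idcr_arousal", "modps_valence")) {
    row <- fits[[nm]]$fixed_effects[2, ]
    expect_gt(row$estimate, 0)
    expect_lt(row$p, 0.01)
  }
  null_fits <- novel_stimulus_validation(broken, broken)
  expect_gt(null_fits$idcr_valence$fixed_effects$p[2], 0.05)
})

test_that("trigger validation rejects for induced cohorts only", {
  mk_records <- function(fb) {
    data.frame(subject_id = rep(sprintf("s%02d", 1:10), each = 20),
               feedback_at_trigger = fb, stringsAsFactors = FALSE)
  }
  mk_table <- function(mu) {
    data.frame(
      subject_id = rep(sprintf("s%02d", 1:10), each = 20),
      trigger_decoded_valence = pmin(0.99, pmax(0.01, rnorm(200, mu, 0.15))),
      accuracy_p = rep(c(0.001, 0.2), each = 100),
      stringsAsFactors = FALSE
    )
  }
  withr::with_seed(64, {
    good <- trigger_validation(mk_records(rnorm(200, 0.9, 0.3)),
                               mk_table(0.7), n_boot = 2000, seed = 65)
    null <- trigger_validation(mk_records(rnorm(200, 0, 0.3)),
                               mk_table(0.5), n_boot = 2000, seed = 65)
  })
  expect_lt(good$median_p, 0.001)
  expect_lt(good$boot_p, 0.02)
  expect_equal(good$n_qualifying, 5)
  expect_gt(null$boot_p, 0.05)
  expect_gt(null$median_p, 0.05)
  ## bootstrap is seeded
  withr::with_seed(66, {
    a <- trigger_validation(mk_records(rnorm(200, 0.9, 0.3)), mk_table(0.7),
                            n_boot = 500, seed = 67)$boot_p
    b <- trigger_validation(mk_records(rnorm(200, 0.9, 0.3)), mk_table(0.7),
                            n_boot = 500, seed = 67)$boot_p
  })
  expect_identical(a, b)
  tab_none <- mk_table(0.7)
  tab_none$accuracy_p <- 0.5
  expect_error(trigger_validation(mk_records(rnorm(200)), tab_none),
               "no subjects")
})

test_that("primary bias model recovers the planted effect structure", {
  tab <- simulate_bias_table(seed = 68)
  fit <- primary_bias_test(tab)
  fe <- fit$fixed_effects
  delta <- fe[fe$term == "trial_typeMod-FS", ]
  expect_lt(abs(delta$estimate - 0.033), 1.96 * delta$se)
  expect_lt(delta$p, 0.05)
  prev <- fe[fe$term == "prev_decoded_valence", ]
  expect_gt(prev$estimate, 0.05) # large positive carry-over (z-scale)
  expect_lt(prev$p, 1e-10)
  expect_gt(fit$r2_adj, 0.55)
  expect_lt(fit$r2_adj, 0.85)
  ## the same structure runs with physio outcomes
  fit_scr <- primary_bias_test(tab, outcome = "scr")
  expect_gt(fit_scr$fixed_effects$p[2], 0.05) # nothing planted on SCR
})

test_that("regulation model recovers the planted transfer slope", {
  tab <- simulate_regulation_table(n_subjects = 39, seed = 69)
  res <- regulation_test(tab)
  row <- res$valence$fixed_effects[res$valence$fixed_effects$term ==
                                     "cue_value", ]
  expect_lt(abs(row$estimate - 0.33), 1.96 * row$se)
  expect_lt(row$p, 0.001)
  lag <- res$valence$fixed_effects[res$valence$fixed_effects$term ==
                                     "recall_lag", ]
  expect_lt(abs(lag$estimate - 0.01), 1.96 * lag$se)
  ## surrogate slopes are null-centred and the paired comparison rejects
  surr <- res$surrogate_valence$fixed_effects
  expect_gt(surr$p[surr$term == "cue_value"], 0.05)
  expect_lt(res$comparison_p_valence, 0.01)
  expect_lt(res$comparison_p_arousal, 0.01)
  expect_equal(nrow(res$slopes), 39)
})

test_that("induction predictors detect planted arousal-slope coupling", {
  tab <- simulate_induction_table(n_subjects = 40, gamma = 0.5, seed = 70)
  fit <- induction_predictor_test(tab, terms = "full")
  row <- fit$fixed_effects[fit$fixed_effects$term == "aro_slope", ]
  expect_gt(row$estimate, 0)
  expect_lt(row$p, 0.05)

  null_tab <- simulate_induction_table(n_subjects = 40, gamma = 0,
                                       seed = 71)
  null_fit <- induction_predictor_test(null_tab, terms = "full")
  null_row <- null_fit$fixed_effects[null_fit$fixed_effects$term ==
                                       "aro_slope", ]
  expect_gt(null_row$p, 0.05)

  ## permuting subject identities breaks the association
  perm_tab <- tab
  withr::with_seed(72, {
    by_sub <- unique(tab[, c("subject_id", "aro_slope")])
    shuf <- setNames(sample(by_sub$aro_slope), by_sub$subject_id)
  })
  perm_tab$aro_slope <- shuf[perm_tab$subject_id]
  perm_fit <- induction_predictor_test(perm_tab, terms = "full")
  perm_row <- perm_fit$fixed_effects[perm_fit$fixed_effects$term ==
                                       "aro_slope", ]
  expect_gt(perm_row$p, 0.05)

  ## aliased designs are rejected with the offending terms named
  bad <- tab
  bad$val_intercept <- bad$val_slope
  expect_error(induction_predictor_test(bad, terms = "full"),
               "aliased")
})
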