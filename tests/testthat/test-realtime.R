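test_that("online detrending passes through early and removes trends", {
  policy <- trigger_policy()
  ## exact line is removed to numerical precision for all i >= 40
  for (i in c(40, 60, 100)) {
    h <- 3 + 0.02 * seq_len(i)
    expect_lt(abs(detrend_online(h[-i], h[i], i, policy)), 1e-9)
  }
  ## below the start index the raw value passes through
  h39 <- rnorm(38)
  expect_identical(detrend_online(h39, 1.7, 39, policy), 1.7)
  ## constant history: the constant is subtracted
  expect_equal(detrend_online(rep(2.5, 49), 3.1, 50, policy), 3.1 - 2.5)
  expect_error(detrend_online(rep(0, 10), 0, 5, policy), "i - 1")
})

test_that("feedback transparency is the clipped affine map", {
  policy <- trigger_policy()
  expect_equal(feedback_alpha(-1.25, policy), 0)
  expect_equal(feedback_alpha(0, policy), 0.5)
  expect_equal(feedback_alpha(1.25, policy), 1)
  expect_equal(feedback_alpha(3, policy), 1)
  expect_equal(feedback_alpha(-10, policy), 0)
})

test_that("trigger threshold holds then decays linearly to zero", {
  policy <- trigger_policy()
  expect_equal(threshold_at(10, policy), 0.8)
  expect_equal(threshold_at(20, policy), 0.8)
  expect_equal(threshold_at(29, policy), 0.4)
  expect_equal(threshold_at(38, policy), 0)
  expect_equal(threshold_at(50, policy), 0)
  expect_error(threshold_at(-1, policy), "non-negative")
})

test_that("the consecutive-criterion state machine fires as specified", {
  policy <- trigger_policy()
  t_grid <- function(n) (seq_len(n) - 1) * 2

  r <- run_state_machine(rep(0.9, 4), t_grid(4), policy)
  expect_equal(r, list(volume = 4L, type = "trigger"))

  r0 <- run_state_machine(rep(0, 25), t_grid(25), policy)
  expect_equal(r0$type, "emergency")
  expect_equal(t_grid(25)[r0$volume], 38) # first volume with t >= 38

  ## a sub-threshold dip resets the count
  rr <- run_state_machine(c(0.9, 0.9, 0.7, 0.9, 0.9, 0.9, 0.9),
                          t_grid(7), policy)
  expect_equal(rr, list(volume = 7L, type = "trigger"))

  ## stepping after a trigger is a usage error
  state <- new_trigger_state()
  for (i in 1:4) state <- step_trigger(state, 0.9, (i - 1) * 2, policy)
  expect_error(step_trigger(state, 0.9, 8, policy), "already triggered")
})

test_that("streaming machine matches the brute-force oracle exactly", {
  policy <- trigger_policy()
  withr::with_seed(13, {
    mismatches <- 0L
    for (rep in 1:200) {
      n <- sample(10:30, 1)
      h <- rnorm(n, mean = runif(1, -0.5, 1.2), sd = 0.5)
      t <- (seq_len(n) - 1) * 2
      a <- run_state_machine(h, t, policy)
      b <- oracle_trigger(h, t, policy)
      if (!identical(a, b)) mismatches <- mismatches + 1L
    }
  })
  expect_identical(mismatches, 0L)
})

test_that("closed-loop trials trigger, terminate, and keep fixed length", {
  catalog <- data.frame(stim_id = "b", valence = 8, arousal = 5.5,
                        stringsAsFactors = FALSE)
  policy <- trigger_policy()
  make_dec <- function(sub) {
    structure(list(weights = sub$pattern_valence, offset = 0,
                   platt_a = NA_real_, platt_b = NA_real_,
                   dimension = "valence", C = 1),
              class = "decoder_model")
  }

  ## perfect self-inducer with a noiseless decoder: criterion trigger
  hi <- subject_profile("hi", n_voxels = 60, noise_sd = 1e-3,
                        controllability = 1, seed = 21)
  out <- run_modfs_trial(hi, make_dec(hi), policy, "b", catalog, seed = 22)
  expect_equal(out$record$trigger_type, "trigger")
  expect_lte(out$record$trigger_time, policy$hold + policy$decay)
  expect_gte(out$record$iti, policy$min_iti)

  ## zero controllability: emergency trigger across seeds
  lo <- subject_profile("lo", n_voxels = 60, noise_sd = 1e-3,
                        controllability = 0, seed = 23)
  ## emergencies dominate (late in the decay even a null process can
  ## briefly clear the near-zero threshold, so not every seed)
  types <- vapply(1:50, function(s) {
    run_modfs_trial(lo, make_dec(lo), policy, "b", catalog,
                    seed = s)$record$trigger_type
  }, character(1))
  expect_gte(mean(types == "emergency"), 0.8)

  ## a full run: exactly one event per trial, fixed trial accounting
  sched <- data.frame(
    onset = c(0, 44, 100), duration = c(44, 44, 44),
    trial_type = "Mod-FS", stim_id = "b", stringsAsFactors = FALSE
  )
  mid <- subject_profile("mid", n_voxels = 60, noise_sd = 0.3,
                         controllability = 0.6, seed = 24)
  loop <- run_modulation_run(sched, mid, catalog, make_dec(mid), policy,
                             scan_duration = 160, seed = 25)
  expect_equal(nrow(loop$records), 3)
  expect_true(all(table(loop$trace$trial[loop$trace$event != "none"]) == 1))
  expect_equal(loop$records$trigger_time + policy$cue_duration +
                 loop$records$iti +
                 ifelse(loop$records$trigger_type == "trigger", 2, 0),
               rep(policy$trial_length, 3))
})
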