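test_that("catalog generation is seeded, feasible, and boomerang-shaped", {
  c1 <- generate_stimulus_catalog(500, seed = 7)
  c2 <- generate_stimulus_catalog(500, seed = 7)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_stimulus_catalog(500, seed = 8)))
  expect_error(generate_stimulus_catalog(59), "n must be >= 60")

  for (n in c(60, 200, 500)) {
    cc <- generate_stimulus_catalog(n, seed = n)
    expect_true(all(cc$valence >= 1 & cc$valence <= 9))
    expect_true(all(cc$arousal >= 1 & cc$arousal <= 9))
    expect_false(anyDuplicated(cc$stim_id) > 0)
    expect_gte(sum(cc$valence >= 7), 30)
    expect_gte(sum(cc$valence <= 2.6), 30)
    pos_int <- cc$valence >= 7 & cc$arousal > 4.6 & cc$arousal < 6.8
    neg_int <- cc$valence <= 2.6 & cc$arousal > 4.6 & cc$arousal < 6.8
    expect_gte(sum(pos_int), 30)
    expect_gte(sum(neg_int), 30)
  }

  big <- generate_stimulus_catalog(5000, seed = 11)
  ct <- cor.test(big$arousal, abs(big$valence - 5))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("volume simulation follows the planted linear encoding model", {
  catalog <- data.frame(stim_id = c("a", "b"), valence = c(5, 9),
                        arousal = c(5, 5), stringsAsFactors = FALSE)
  sub0 <- subject_profile("s0", n_voxels = 40, noise_sd = 0, seed = 1)

  ## midpoint-score stimulus with zero noise and drift: data identically 0
  sch_a <- data.frame(onset = 10, duration = 2, trial_type = "Id-PS",
                      stim_id = "a", stringsAsFactors = FALSE)
  vs0 <- simulate_volume_series(sch_a, sub0, catalog, 60, drift_sd = 0,
                                seed = 2)
  expect_equal(max(abs(vs0$data)), 0)
  ## with drift only, data equals the drift term (rank-1 in time)
  vsd <- simulate_volume_series(sch_a, sub0, catalog, 60, drift_sd = 0.05,
                                seed = 2)
  expect_equal(vsd$data[, 1], rep(0, 40)) # zero at first volume
  expect_equal(vsd$data[, 11], 10 * (vsd$data[, 2] - vsd$data[, 1]))

  ## extreme stimulus: projection onto the planted pattern equals the
  ## analytic HRF convolution; peak at onset + 6 s
  sch_b <- data.frame(onset = 10, duration = 2, trial_type = "Id-PS",
                      stim_id = "b", stringsAsFactors = FALSE)
  vs <- simulate_volume_series(sch_b, sub0, catalog, 60, drift_sd = 0,
                               seed = 3)
  proj <- drop(crossprod(sub0$pattern_valence, vs$data))
  impulses <- replace(numeric(30), 10 / 2 + 1, 1)
  expected <- affectloop:::convolve_hrf(impulses, 2)
  expect_lt(max(abs(proj - expected)), 1e-9)
  expect_equal((which.max(proj) - 1) * 2, 10 + 6)

  ## two seeds differ only in the zero-mean noise term
  subn <- subject_profile("sn", n_voxels = 40, noise_sd = 0.7, seed = 4)
  v1 <- simulate_volume_series(sch_b, subn, catalog, 60, drift_sd = 0,
                               seed = 5)
  v2 <- simulate_volume_series(sch_b, subn, catalog, 60, drift_sd = 0,
                               seed = 6)
  d <- v1$data - v2$data
  expect_lt(abs(mean(d)), 0.05)
  expect_gt(sd(d), 0.5)

  expect_error(
    simulate_volume_series(
      data.frame(onset = 58, duration = 10, trial_type = "Id-PS",
                 stim_id = "a"), sub0, catalog, 60),
    "past scan"
  )
})

test_that("self-induction is a seeded, bounded, mean-reverting process", {
  lo <- subject_profile("lo", n_voxels = 10, controllability = 0, seed = 1)
  hi <- subject_profile("hi", n_voxels = 10, controllability = 1, seed = 1)

  expect_identical(simulate_selfinduction(hi, 38, seed = 9),
                   simulate_selfinduction(hi, 38, seed = 9))

  means_lo <- vapply(1:100, function(s) {
    mean(simulate_selfinduction(lo, 38, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(means_lo)), 0.1)

  late_ok <- vapply(1:200, function(s) {
    traj <- simulate_selfinduction(hi, 120, seed = s)
    mean(tail(traj, 10)) >= 0.8
  }, logical(1))
  expect_gte(mean(late_ok), 0.9)

  for (s in 1:50) {
    traj <- simulate_selfinduction(hi, 38, seed = s, innovation_sd = 0.6)
    expect_true(all(traj >= -1.25 & traj <= 1.25))
  }
  expect_error(simulate_selfinduction(hi, 1, tr = 2), "duration")
})

test_that("physiology responds linearly to scaled scores", {
  cc <- generate_stimulus_catalog(5000, seed = 2)
  ## zero gains: pure noise, no recoverable slope
  s0 <- subject_profile("p0", n_voxels = 10, physio_gain_cemg = 0,
                        physio_gain_scr = 0, seed = 1)
  ph0 <- simulate_physio(cc, s0, seed = 3)
  f <- summary(lm(ph0$cemg ~ cc$valence))
  expect_gt(f$coefficients[2, 4], 0.01)
  ## zero noise: exactly linear with the stated gains
  s1 <- subject_profile("p1", n_voxels = 10, seed = 1)
  ph1 <- simulate_physio(cc[1:50, ], s1, noise_sd = 0, seed = 4)
  expect_equal(ph1$cemg, 0.11 * (cc$valence[1:50] - 5) / 4)
  expect_equal(ph1$scr, 0.07 * (cc$arousal[1:50] - 5) / 4)
  ## seeded determinism
  expect_identical(simulate_physio(cc[1:20, ], s1, seed = 5),
                   simulate_physio(cc[1:20, ], s1, seed = 5))
})

test_that("schedules respect the TR grid and round-trip through TSV", {
  sch <- make_id_schedule(sprintf("p%02d", 1:20), sprintf("c%02d", 1:6),
                          run_duration = 300, seed = 3)
  expect_length(sch, 2)
  for (s in sch) {
    expect_true(all(diff(s$onset) > 0))
    expect_true(all(s$duration > 0))
    expect_true(all(s$onset %% 2 == 0))
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(sch[[1]], path)
  expect_equal(read_events_tsv(path), sch[[1]])

  mod <- make_mod_schedule(sprintf("m%02d", 1:8), sprintf("f%02d", 1:4),
                           run_duration = 400, seed = 4)
  expect_true(all(vapply(mod, function(s) {
    all(s$duration[s$trial_type == "Mod-FS"] == 44)
  }, logical(1))))
})

test_that("volume series round-trips through the TSV array container", {
  vs <- volume_series(matrix(rnorm(60), 10, 6), tr = 2, t0 = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_volume_series(vs, path)
  back <- read_volume_series(path)
  expect_equal(back$data, vs$data, tolerance = 1e-12)
  expect_equal(back$tr, 2)
  expect_equal(back$t0, 4)
  expect_error(volume_series(matrix(c(1, NA), 1, 2)), "NA")
})
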