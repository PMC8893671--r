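test_that("maxspan sampling is greedy farthest-point dispersion", {
  cc <- corner_catalog()
  ## n = total: everything selected
  expect_setequal(maxspan_sample(cc, 5, seed = 1), cc$stim_id)
  ## first pick is the centre point; second is some corner (all corners
  ## are brute-force-equidistant from the centre)
  picks <- maxspan_sample(cc, 2, seed = 1)
  expect_identical(picks[1], "mid")
  expect_true(picks[2] %in% c("c11", "c19", "c91", "c99"))

  ## dispersion beats random subsets: min pairwise distance of the greedy
  ## 30-subset exceeds the median over 1000 random 30-subsets
  cc2 <- generate_stimulus_catalog(300, seed = 5)
  min_pair_d <- function(ids) {
    m <- as.matrix(cc2[match(ids, cc2$stim_id), c("valence", "arousal")])
    min(dist(sweep(sweep(m, 2, apply(m, 2, min)), 2,
                   apply(cc2[, c("valence", "arousal")], 2, function(x) {
                     diff(range(x))
                   }), "/")))
  }
  greedy <- min_pair_d(maxspan_sample(cc2, 30, seed = 6))
  rand <- withr::with_seed(7, {
    replicate(1000, min_pair_d(sample(cc2$stim_id, 30)))
  })
  expect_gte(greedy, median(rand))

  ## row-order invariance up to seeded tie-breaking (jittered, tie-free)
  perm <- withr::with_seed(8, sample.int(nrow(cc2)))
  expect_setequal(maxspan_sample(cc2, 15, seed = 9),
                  maxspan_sample(cc2[perm, ], 15, seed = 9))
  expect_error(maxspan_sample(cc2[0, ], 1), "empty|\\[1,")
})

test_that("polar subsets satisfy valence bounds and arousal equivalence", {
  ## already-matched tails: no shrinking, full-range window
  matched <- data.frame(
    stim_id = sprintf("m%03d", 1:60),
    valence = rep(c(7.5, 2), each = 30),
    arousal = rep(seq(4.8, 6.6, length.out = 30), 2),
    stringsAsFactors = FALSE
  )
  ps0 <- polar_subsets(matched, n_per_side = 30, seed = 1)
  expect_equal(ps0$arousal_window, range(matched$arousal))
  expect_gt(ps0$equivalence_p, 0.05)

  ## planted arousal mismatch: window shrinks strictly and matching holds
  withr::with_seed(2, {
    planted <- data.frame(
      stim_id = sprintf("q%03d", 1:300),
      valence = rep(c(7.6, 2.1), each = 150),
      arousal = pmin(9, pmax(1, rnorm(300, rep(c(5.9, 5.1), each = 150),
                                      0.7))),
      stringsAsFactors = FALSE
    )
  })
  ps <- polar_subsets(planted, n_per_side = 20, seed = 3)
  full <- range(planted$arousal)
  expect_gt(ps$equivalence_p, 0.05)
  expect_gt(ps$arousal_window[1], full[1])
  expect_lt(ps$arousal_window[2], full[2])
  sel <- planted[planted$stim_id %in% c(ps$positive, ps$negative), ]
  expect_true(all(sel$valence[sel$stim_id %in% ps$positive] >= 7))
  expect_true(all(sel$valence[sel$stim_id %in% ps$negative] <= 2.6))
  expect_true(all(sel$arousal >= ps$arousal_window[1] &
                    sel$arousal <= ps$arousal_window[2]))

  ## extreme separation with no overlap collapses to the documented error
  hopeless <- data.frame(
    stim_id = sprintf("h%03d", 1:80),
    valence = rep(c(8, 2), each = 40),
    arousal = rep(c(8, 2), each = 40) + rep(seq(-0.3, 0.3, length.out = 40), 2),
    stringsAsFactors = FALSE
  )
  expect_error(polar_subsets(hopeless, n_per_side = 40), "infeasible")
})

test_that("trial assignment is balanced, seeded, and partitioning", {
  cc <- generate_stimulus_catalog(500, seed = 10)
  ps <- polar_subsets(cc, n_per_side = 30, seed = 11)
  a <- assign_trials(ps, n_ps = 40, n_fs = 20, seed = 12)
  tab <- table(a$trial_type, a$polarity)
  expect_equal(unname(tab["Mod-PS", ]), c(20, 20))
  expect_equal(unname(tab["Mod-FS", ]), c(10, 10))
  expect_identical(a, assign_trials(ps, n_ps = 40, n_fs = 20, seed = 12))
  expect_setequal(a$stim_id, c(ps$positive, ps$negative))
  expect_false(anyDuplicated(a$stim_id) > 0)
  expect_error(assign_trials(ps, n_ps = 41, n_fs = 20), "even")
  expect_error(assign_trials(ps, n_ps = 60, n_fs = 20), "not enough")
})
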