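test_that("max-margin training honours margins and symmetries", {
  X <- rbind(c(1, 0), c(-1, 0))
  y <- c(1L, -1L)
  fit <- train_linear_classifier(X, y, standardize = FALSE)
  h <- hyperplane_distance(fit, X)
  expect_identical(sign(h), c(1, -1))
  ## canonical margin at the support vectors
  expect_equal(abs(h), c(1, 1), tolerance = 1e-8)

  ## label flip negates the hyperplane (solver tolerance)
  withr::with_seed(1, {
    Xr <- matrix(rnorm(40 * 6), 40, 6)
    yr <- rep(c(1L, -1L), 20)
  })
  f1 <- train_linear_classifier(Xr, yr)
  f2 <- train_linear_classifier(Xr, -yr)
  expect_lt(max(abs(f1$weights + f2$weights)), 1e-6)
  expect_lt(abs(f1$offset + f2$offset), 1e-6)

  ## unlabelled rows are ignored
  f3 <- train_linear_classifier(rbind(X, c(50, 50)), c(y, 0L),
                                standardize = FALSE)
  expect_equal(f3$weights, fit$weights, tolerance = 1e-8)
  expect_error(train_linear_classifier(X, c(1L, 1L)), "both classes")
})

test_that("planted patterns are recovered at vanishing noise", {
  world <- planted_features(n = 200, p = 30, target_acc = 0.8, seed = 2)
  X_clean <- outer(world$amps, world$pattern) +
    matrix(rnorm(200 * 30, 0, 1e-4), 200, 30)
  ## standardization is skipped: at vanishing noise the per-voxel SDs are
  ## proportional to the pattern itself and would distort the direction
  fit <- train_linear_classifier(X_clean, world$y, standardize = FALSE)
  cosine <- sum(fit$weights * world$pattern) /
    sqrt(sum(fit$weights^2))
  expect_gt(cosine, 0.95)
})

test_that("hyperplane distance is the affine decision value", {
  fit <- train_linear_classifier(rbind(c(1, 0), c(-1, 0)), c(1L, -1L),
                                 standardize = FALSE)
  expect_equal(hyperplane_distance(fit, c(0, 5)), 0)
  x <- c(0.3, -0.7)
  expect_equal(hyperplane_distance(fit, 3 * x) - fit$offset,
               3 * (hyperplane_distance(fit, x) - fit$offset))
  expect_error(hyperplane_distance(fit, c(1, 2, 3)), "mismatch")
})

test_that("Platt scaling is monotone, symmetric, and scale-stable", {
  withr::with_seed(3, {
    y <- rep(c(1, -1), each = 500)
    h <- rnorm(1000, mean = y * 1.2, sd = 1)
  })
  ab <- fit_platt(h, y)
  expect_lt(ab["platt_a"], 0)
  pr0 <- 1 / (1 + exp(ab["platt_b"])) # Pr at h = 0
  expect_equal(unname(pr0), 0.5, tolerance = 0.05)

  ## well-separated classes: strictly monotone map, confident at max h
  withr::with_seed(4, {
    hs <- c(rnorm(200, 3), rnorm(200, -3))
    ys <- rep(c(1, -1), each = 200)
  })
  ab2 <- fit_platt(hs, ys)
  grid <- seq(min(hs), max(hs), length.out = 50)
  pg <- 1 / (1 + exp(ab2["platt_a"] * grid + ab2["platt_b"]))
  expect_true(all(diff(pg) > 0))
  expect_gt(max(pg), 0.9)

  ## rescaling h rescales platt_a, leaving probabilities unchanged
  ab10 <- fit_platt(10 * h, y)
  p1 <- 1 / (1 + exp(ab["platt_a"] * h + ab["platt_b"]))
  p2 <- 1 / (1 + exp(ab10["platt_a"] * 10 * h + ab10["platt_b"]))
  expect_lt(max(abs(p1 - p2)), 1e-3)

  expect_error(fit_platt(rep(1, 10), rep(c(1, -1), 5)), "degenerate")
})

test_that("decode applies the calibrated logistic map", {
  world <- planted_features(n = 120, p = 10, target_acc = 0.9, seed = 5)
  fit <- train_linear_classifier(world$X, world$y)
  expect_error(decode(fit, world$X), "not calibrated")
  fit <- calibrate_decoder(fit, world$X, world$y)
  pr <- decode(fit, world$X)
  h <- hyperplane_distance(fit, world$X)
  expect_equal(pr, 1 / (1 + exp(fit$platt_a * h + fit$platt_b)))
  expect_true(all(diff(pr[order(h)]) >= 0))
})

test_that("Platt probabilities are calibrated on held-out data", {
  ## reliability-diagram slope within [0.8, 1.2] at n = 2000
  withr::with_seed(6, {
    y_tr <- rep(c(1, -1), each = 1000)
    h_tr <- rnorm(2000, y_tr * 0.8, 1)
    y_te <- rep(c(1, -1), each = 1000)
    h_te <- rnorm(2000, y_te * 0.8, 1)
  })
  ab <- fit_platt(h_tr, y_tr)
  pr <- 1 / (1 + exp(ab["platt_a"] * h_te + ab["platt_b"]))
  bins <- cut(pr, breaks = quantile(pr, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  emp <- tapply(y_te == 1, bins, mean)
  mid <- tapply(pr, bins, mean)
  slope <- coef(lm(emp ~ mid))[2]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("beta-series extraction solves the least-squares-all model", {
  withr::with_seed(7, {
    p <- 15
    n_vols <- 120
    onsets <- c(10, 30, 52, 74, 96, 118, 140, 170, 190, 210)
    amps <- rnorm(10, 0, 1)
    patterns <- matrix(rnorm(p * 10), p, 10)
  })
  signal <- matrix(0, p, n_vols)
  for (j in seq_along(onsets)) {
    imp <- replace(numeric(n_vols), onsets[j] / 2 + 1, amps[j])
    signal <- signal + outer(patterns[, j], affectloop:::convolve_hrf(imp, 2))
  }
  ## add known drift + intercept; the design models both
  drift <- outer(rep(0.01, p), seq_len(n_vols) - 1)
  series <- volume_series(signal + drift + 0.3, tr = 2)
  events <- data.frame(onset = onsets, tag = sprintf("e%02d", 1:10))
  bs <- extract_beta_series(series, events)
  for (j in seq_along(onsets)) {
    expect_equal(bs$beta[, j], amps[j] * patterns[, j], tolerance = 1e-6)
  }
  ## zero series: all betas zero
  bs0 <- extract_beta_series(volume_series(matrix(0, p, n_vols), tr = 2),
                             events)
  expect_equal(max(abs(bs0$beta)), 0)
  ## permuting events permutes betas identically
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 10, 8)
  bsp <- extract_beta_series(series, events[perm, ])
  expect_equal(unname(bsp$beta), unname(bs$beta[, perm]), tolerance = 1e-10)
  ## duplicated onsets are collinear and named in the error
  dup <- data.frame(onset = c(10, 10), tag = c("x", "y"))
  expect_error(extract_beta_series(series, dup), "collinear.*y")
  ## off-grid onsets snap to the nearest volume (always within tr/2)
  snap <- extract_beta_series(series, data.frame(onset = 10.4, tag = "x"))
  exact <- extract_beta_series(series, data.frame(onset = 10, tag = "x"))
  expect_equal(snap$beta, exact$beta)
})

test_that("within-subject accuracy uses the exact binomial tail", {
  world <- planted_features(n = 90, p = 8, target_acc = 0.999, seed = 8)
  fit <- train_linear_classifier(world$X, world$y)
  res <- within_subject_accuracy(fit, world$X, world$y)
  expect_equal(res$accuracy, 1)
  expect_equal(res$p, 0.5^90)
  ## tail sum computed independently
  tail_sum <- function(k, n) sum(choose(n, k:n)) / 2^n
  expect_equal(pbinom(53, 90, 0.5, lower.tail = FALSE), tail_sum(54, 90))
  expect_gt(pbinom(44, 90, 0.5, lower.tail = FALSE), 0.05)
  expect_error(within_subject_accuracy(fit, world$X, rep(0L, 90)), "empty")
})

test_that("reliable stimulus selection ranks by inter-subject agreement", {
  withr::with_seed(9, {
    p <- 30
    shared <- matrix(rnorm(p * 10), p, 10) # 10 stimuli, shared maps
    make_subj <- function() {
      b <- shared + matrix(rnorm(p * 10, 0, 0.5), p, 10)
      b[, 1] <- shared[, 1]  # stimulus 1: identical across subjects
      b[, 10] <- rnorm(p)    # stimulus 10: pure idiosyncratic noise
      colnames(b) <- sprintf("s%02d", 1:10)
      structure(list(beta = b), class = "beta_series")
    }
    subs <- list(make_subj(), make_subj(), make_subj())
  })
  keep <- reliable_stimulus_set(subs, fraction = 0.5)
  expect_length(keep, 5)
  expect_false("s10" %in% keep)
  ## the identical-across-subjects stimulus has reliability 1: always kept
  expect_identical(keep[1], "s01")
  expect_error(reliable_stimulus_set(subs[1], 0.5), "2 subjects")
})
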