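## Shared fixtures and independent oracles, built in code at test time.

## tiny catalog of known geometry: four corners plus centre
corner_catalog <- function() {
  data.frame(
    stim_id = c("c11", "c19", "c91", "c99", "mid"),
    valence = c(1, 1, 9, 9, 5),
    arousal = c(1, 9, 1, 9, 5),
    stringsAsFactors = FALSE
  )
}

## noise level at which an oracle (Bayes) classifier that knows the planted
## pattern reaches `target` expected accuracy on amplitudes `amps`
oracle_noise_sd <- function(amps, target = 0.8) {
  stats::uniroot(function(s) mean(stats::pnorm(abs(amps) / s)) - target,
                 c(0.01, 10))$root
}

## planted-pattern feature set in the decoding model's own terms:
## x_i = amp_i * pattern + noise
planted_features <- function(n = 360, p = 20, target_acc = 0.8,
                             seed = 1) {
  withr::with_seed(seed, {
    v <- pmin(9, pmax(1, c(rnorm(n / 2, 7.3, 0.9), rnorm(n / 2, 2.3, 0.9))))
    amps <- (v - 5) / 4
    sigma <- oracle_noise_sd(amps, target_acc)
    pattern <- rnorm(p)
    pattern <- pattern / sqrt(sum(pattern^2))
    list(
      X = outer(amps, pattern) + matrix(rnorm(n * p, 0, sigma), n, p),
      y = as.integer(sign(v - 5)),
      amps = amps,
      pattern = pattern,
      sigma = sigma,
      oracle_acc = mean(stats::pnorm(abs(amps) / sigma))
    )
  })
}

## independent brute-force oracle for the trigger state machine: rescans
## the full detrended-distance sequence with explicit bookkeeping
oracle_trigger <- function(h, t, policy) {
  consec <- 0L
  for (i in seq_along(h)) {
    thr <- if (t[i] <= policy$hold) {
      policy$threshold0
    } else {
      max(0, policy$threshold0 * (1 - (t[i] - policy$hold) / policy$decay))
    }
    if (h[i] >= thr) consec <- consec + 1L else consec <- 0L
    if (consec >= policy$n_consecutive) {
      return(list(volume = i, type = "trigger"))
    }
    if (t[i] >= policy$hold + policy$decay) {
      return(list(volume = i, type = "emergency"))
    }
  }
  list(volume = NA_integer_, type = "none")
}

## drive step_trigger over a full sequence, returning the event volume/type
run_state_machine <- function(h, t, policy) {
  state <- new_trigger_state()
  for (i in seq_along(h)) {
    state <- step_trigger(state, h[i], t[i], policy)
    if (!is.na(state$event)) return(list(volume = i, type = state$event))
  }
  list(volume = NA_integer_, type = "none")
}
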