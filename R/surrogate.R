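#' Decode every volume of a resting-state series
#'
#' @param series A [volume_series()] of preprocessed resting data.
#' @param model A calibrated `decoder_model`.
#' @return Per-volume decoded probabilities.
#' @export
decode_resting <- function(series, model) {
  stopifnot(inherits(series, "volume_series"))
  decode(model, t(series$data))
}

#' Sample surrogate cued-recall trials from decoded resting data
#'
#' Draws `n` TR-aligned onsets uniformly at random, without replacement
#' and without overlap of the trial footprints, and extracts the decoded
#' value at the cue volume plus the 4 decoded values of the recall window
#' (cue 2 s + cue-response 2 s + recall 8 s, mirroring cued-recall trial
#' timing: the recall window starts 4 s after cue onset).
#'
#' @param decoded Per-volume decoded probabilities (see
#'   [decode_resting()]).
#' @param n Number of surrogate trials (default 30).
#' @param tr Repetition time in seconds.
#' @param seed Integer seed.
#' @return A `surrogate_trials` data.frame in long format: columns
#'   `trial`, `onset`, `cue_value`, `recall_lag` (1-4), `recall_value`.
#' @export
sample_surrogate_trials <- function(decoded, n = 30, tr = 2, seed = NULL) {
  assert_scalar_number(n, "n", lower = 1)
  n_vols <- length(decoded)
  footprint <- round(12 / tr) # cue + cue-response + recall, in volumes
  last_start <- n_vols - footprint + 1L
  if (last_start < n) {
    stop("resting series too short for ", n, " surrogate trials",
         call. = FALSE)
  }
  if (last_start - (n - 1L) * (footprint - 1L) < n) {
    stop("could not place ", n, " non-overlapping surrogate trials",
         call. = FALSE)
  }
  with_seed(seed, {
    ## uniform draw over non-overlapping placements: sample sorted starts
    ## with minimum separation via the gap transform
    x <- sort(sample.int(last_start - (n - 1L) * (footprint - 1L), n))
    starts <- x + (seq_len(n) - 1L) * (footprint - 1L)
    recall_off <- round(4 / tr) # recall window starts 4 s after cue onset
    out <- do.call(rbind, lapply(seq_along(starts), function(i) {
      s <- starts[i]
      data.frame(
        trial = i,
        onset = (s - 1L) * tr,
        cue_value = decoded[s],
        recall_lag = 1:4,
        recall_value = decoded[s + recall_off + 0:3],
        stringsAsFactors = FALSE
      )
    }))
    class(out) <- c("surrogate_trials", class(out))
    out
  })
}
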