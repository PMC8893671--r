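#' Canonical double-gamma hemodynamic response function
#'
#' Impulse response linking a neural event at `t = 0` to the measured BOLD
#' signal: a response gamma peaking at 6 s minus an undershoot gamma peaking
#' at 16 s with a 6:1 peak-to-undershoot ratio, scaled to unit peak
#' amplitude. The response is effectively zero by 32 s.
#'
#' @param t Time in seconds since the event; non-negative, vectorized.
#' @return Dimensionless response amplitude, same length as `t`.
#' @examples
#' hrf(c(0, 6, 16, 32))
#' @export
hrf <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("'t' must be finite numeric", call. = FALSE)
  }
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  ## gamma variates in mode-parameterized form: (t/d)^a exp(-(t-d)/b) peaks
  ## at t = d = a*b with unit amplitude
  peak <- (t / 6)^6 * exp(-(t - 6))
  under <- (t / 16)^16 * exp(-(t - 16))
  peak - under / 6
}

## HRF sampled on the TR grid (k = 0, 1, ... up to 32 s support)
hrf_kernel <- function(tr, normalize = FALSE) {
  assert_scalar_number(tr, "tr", lower = 1e-6)
  k <- hrf(seq(0, 32, by = tr))
  if (normalize) k <- k / sum(k)
  k
}

## convolve a per-TR impulse train with the HRF kernel, truncated to the
## train's length
convolve_hrf <- function(impulses, tr, normalize = FALSE) {
  kern <- hrf_kernel(tr, normalize = normalize)
  n <- length(impulses)
  full <- stats::convolve(c(impulses, numeric(length(kern))), rev(kern),
                          type = "open")
  full[seq_len(n)]
}

#' Build a signed HRF class regressor from stimulus onsets and scores
#'
#' Forms an impulse train whose amplitude at each onset is the signed
#' distance of the stimulus' normative score from the middle Likert score
#' (5), convolves it with [hrf()], and samples the result at volume
#' acquisition times. A score of exactly 5 contributes nothing.
#'
#' @param onsets Stimulus onsets in seconds from scan start.
#' @param scores Normative Likert scores in `[1, 9]`, one per onset.
#' @param tr Repetition time in seconds.
#' @param n_vols Number of volumes in the scan.
#' @return Numeric vector of length `n_vols`.
#' @export
build_class_regressor <- function(onsets, scores, tr, n_vols) {
  assert_scalar_number(tr, "tr", lower = 1e-6)
  assert_scalar_number(n_vols, "n_vols", lower = 1)
  if (length(onsets) != length(scores)) {
    stop("'onsets' and 'scores' must have equal length", call. = FALSE)
  }
  if (length(scores) && (any(scores < 1) || any(scores > 9))) {
    stop("'scores' must lie in [1, 9]", call. = FALSE)
  }
  scan_len <- n_vols * tr
  if (length(onsets) && (any(onsets < 0) || any(onsets >= scan_len))) {
    stop("onsets must lie within the scan", call. = FALSE)
  }
  idx <- onsets / tr
  if (length(idx) && any(abs(idx - round(idx)) > 0.5 + 1e-9)) {
    stop("onset misaligned with the TR grid by more than tr/2", call. = FALSE)
  }
  impulses <- numeric(n_vols)
  for (j in seq_along(onsets)) {
    i <- round(idx[j]) + 1L
    impulses[i] <- impulses[i] + (scores[j] - 5)
  }
  convolve_hrf(impulses, tr)
}

#' Threshold a class regressor into per-volume labels
#'
#' Volumes whose regressor value reaches `theta` times the maximum absolute
#' regressor value are labelled `+1` (positive side) or `-1` (negative
#' side); all remaining volumes are unlabelled (`0`). An all-zero regressor
#' yields no labels.
#'
#' @param regressor Per-volume signed regressor, e.g. from
#'   [build_class_regressor()].
#' @param theta Fraction of the maximum absolute value in `(0, 1)` used as
#'   the labelling threshold (default 0.2).
#' @return Integer vector of labels in `{-1, 0, 1}`.
#' @export
label_volumes <- function(regressor, theta = 0.2) {
  assert_scalar_number(theta, "theta")
  if (theta <= 0 || theta >= 1) stop("'theta' must be in (0,1)", call. = FALSE)
  m <- max(abs(regressor))
  labels <- integer(length(regressor))
  if (m == 0) return(labels)
  labels[regressor >= theta * m] <- 1L
  labels[regressor <= -theta * m] <- -1L
  labels
}
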