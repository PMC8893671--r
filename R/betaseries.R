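#' Build beta-series event lists from a schedule
#'
#' Helper constructing the `(onset, tag)` event table consumed by
#' [extract_beta_series()]. Passive and cue rows contribute one event at
#' trial onset; `Id-CR-recall` rows contribute one event per recall volume
#' (tagged `<stim>:recall1..4`); `Mod-FS` rows can additionally contribute
#' the pre-cue (trigger-volume) event 2 s before the cue, and `Mod-PS`
#' rows the volume immediately before trial onset.
#'
#' @param schedule Events `data.frame`.
#' @param types Trial types to include.
#' @param pre_cue Add `:pre` events one TR before each included cue
#'   (default `FALSE`).
#' @param tr Repetition time, seconds.
#' @param cue_onsets Optional named numeric vector giving realized cue
#'   onsets for Mod-FS rows (seconds), e.g. trigger-determined; names are
#'   stim_ids.
#' @return `data.frame` with columns `onset`, `tag`, `stim_id`,
#'   `trial_type`.
#' @export
events_from_schedule <- function(schedule, types = c("Id-PS", "Mod-PS"),
                                 pre_cue = FALSE, tr = 2,
                                 cue_onsets = NULL) {
  rows <- list()
  add <- function(onset, tag, sid, ty) {
    rows[[length(rows) + 1L]] <<- data.frame(
      onset = onset, tag = tag, stim_id = sid, trial_type = ty,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(schedule))) {
    ty <- schedule$trial_type[r]
    if (!ty %in% types) next
    sid <- schedule$stim_id[r]
    onset <- schedule$onset[r]
    if (ty == "Id-CR-recall") {
      for (j in 1:4) {
        add(onset + (j - 1) * tr, sprintf("%s:recall%d", sid, j), sid, ty)
      }
    } else if (ty == "Mod-FS") {
      cue <- if (!is.null(cue_onsets) && sid %in% names(cue_onsets)) {
        unname(cue_onsets[sid])
      } else {
        onset + schedule$duration[r] - 6 # default: cue after full decay
      }
      if (pre_cue) add(cue - tr, paste0(sid, ":pre"), sid, ty)
      add(cue, sid, sid, ty)
    } else {
      if (pre_cue) add(onset - tr, paste0(sid, ":pre"), sid, ty)
      add(onset, sid, sid, ty)
    }
  }
  out <- do.call(rbind, rows)
  out[out$onset >= 0, , drop = FALSE]
}

#' Extract single-trial beta maps (beta-series) from a volume series
#'
#' Least-squares-all model: a single design containing one HRF-convolved
#' unit-amplitude regressor per event plus an intercept and a linear drift
#' column, solved voxelwise by ordinary least squares. The returned betas
#' are the per-event coefficients.
#'
#' @param series A [volume_series()].
#' @param events `data.frame` with columns `onset` (seconds) and `tag`
#'   (unique event labels), e.g. from [events_from_schedule()].
#' @return An object of class `beta_series`: list with `beta` (voxels x
#'   events matrix, columns named by tag) and `events`.
#' @export
extract_beta_series <- function(series, events) {
  stopifnot(inherits(series, "volume_series"))
  if (!all(c("onset", "tag") %in% names(events))) {
    stop("events must have columns onset and tag", call. = FALSE)
  }
  if (anyDuplicated(events$tag)) {
    stop("event tags must be unique", call. = FALSE)
  }
  tr <- series$tr
  n_vols <- ncol(series$data)
  scan_len <- n_vols * tr
  if (any(events$onset < 0 | events$onset >= scan_len)) {
    stop("events must lie within the scan", call. = FALSE)
  }
  X <- matrix(0, n_vols, nrow(events) + 2L)
  X[, 1] <- 1
  X[, 2] <- seq_len(n_vols) - 1
  for (j in seq_len(nrow(events))) {
    idx <- events$onset[j] / tr
    if (abs(idx - round(idx)) > 0.5 + 1e-9) {
      stop("event onset misaligned with the TR grid", call. = FALSE)
    }
    imp <- numeric(n_vols)
    imp[round(idx) + 1L] <- 1
    X[, j + 2L] <- convolve_hrf(imp, tr)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    aliased_tags <- events$tag[aliased[aliased > 2] - 2L]
    stop("rank-deficient beta-series design; collinear events: ",
         paste(aliased_tags, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrX, t(series$data))
  beta <- t(coefs[-(1:2), , drop = FALSE])
  colnames(beta) <- events$tag
  structure(list(beta = beta, events = events), class = "beta_series")
}

#' @exportS3Method base::print
print.beta_series <- function(x, ...) {
  cat(sprintf("<beta_series: %d voxels x %d events>\n",
              nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

#' Select stimuli with reliable brain-state activations across subjects
#'
#' Proxy reliability criterion: for each stimulus, reliability is the mean
#' inter-subject pairwise Pearson correlation of its beta maps; the top
#' `fraction` of stimuli by reliability is returned.
#'
#' @param beta_list List of `beta_series` (one per subject) whose columns
#'   are tagged by stimulus id.
#' @param fraction Proportion of stimuli to retain (default 0.5).
#' @return Character vector of retained stimulus ids, ordered by
#'   decreasing reliability.
#' @export
reliable_stimulus_set <- function(beta_list, fraction = 0.5) {
  if (length(beta_list) < 2L) {
    stop("reliability requires at least 2 subjects", call. = FALSE)
  }
  assert_scalar_number(fraction, "fraction", lower = 0, upper = 1)
  stims <- Reduce(intersect, lapply(beta_list, function(b) colnames(b$beta)))
  rel <- vapply(stims, function(s) {
    maps <- sapply(beta_list, function(b) b$beta[, s])
    cm <- cor(maps)
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  n_keep <- round(fraction * length(stims))
  names(sort(rel, decreasing = TRUE))[seq_len(n_keep)]
}
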