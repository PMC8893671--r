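#' Maximal-span sampling of the valence-arousal plane
#'
#' Greedy farthest-point dispersion on min-max-normalized valence/arousal
#' coordinates: the first pick is the catalog item nearest the centre of
#' the normalized plane; each subsequent pick maximizes the minimum
#' Euclidean distance to the items already picked. Exact ties are broken
#' by a seeded random draw, so the selection is invariant to catalog row
#' order up to tie-breaking.
#'
#' @param catalog Stimulus catalog `data.frame`.
#' @param n Number of items to select (`n <= nrow(catalog)`).
#' @param seed Integer seed (used only to break exact ties).
#' @return Character vector of `n` selected `stim_id`s.
#' @export
maxspan_sample <- function(catalog, n, seed = NULL) {
  validate_catalog(catalog)
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  assert_scalar_number(n, "n", lower = 1, upper = nrow(catalog))
  n <- as.integer(n)
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) < .Machine$double.eps) return(rep(0.5, length(x)))
    (x - r[1]) / diff(r)
  }
  pts <- cbind(norm01(catalog$valence), norm01(catalog$arousal))
  with_seed(seed, {
    pick_min <- function(d) {
      ## seeded tie-break over indices attaining the minimum
      cand <- which(d <= min(d) + 1e-12)
      if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    }
    pick_max <- function(d) {
      cand <- which(d >= max(d) - 1e-12)
      if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    }
    centre_d <- sqrt((pts[, 1] - 0.5)^2 + (pts[, 2] - 0.5)^2)
    sel <- pick_min(centre_d)
    mind <- sqrt((pts[, 1] - pts[sel, 1])^2 + (pts[, 2] - pts[sel, 2])^2)
    while (length(sel) < n) {
      mind[sel] <- -Inf
      nxt <- pick_max(mind)
      sel <- c(sel, nxt)
      d_new <- sqrt((pts[, 1] - pts[nxt, 1])^2 + (pts[, 2] - pts[nxt, 2])^2)
      mind <- pmin(mind, d_new)
    }
    catalog$stim_id[sel]
  })
}

#' Extreme-valence polar subsets with iterative arousal matching
#'
#' Starts from the valence tails (`v >= 7` positive, `v <= 2.6` negative)
#' with the arousal window unrestricted, then repeatedly tests the
#' group arousal difference with a two-sided rank-sum (Wilcoxon) test and,
#' while `p <= alpha`, shrinks the arousal window symmetrically inward by
#' 0.1 Likert units toward the pooled arousal median, dropping excluded
#' items. When the sides are arousal-equivalent it draws `n_per_side`
#' items uniformly at random from each side.
#'
#' @param catalog Stimulus catalog `data.frame`.
#' @param n_per_side Items to sample per side (default 30).
#' @param alpha Significance level for the rank-sum equivalence check
#'   (default 0.05).
#' @param seed Integer seed for the final uniform draws.
#' @return An object of class `polar_subsets`: list with `positive`,
#'   `negative` (stim_id vectors), `arousal_window` (length-2 numeric) and
#'   `equivalence_p`.
#' @export
polar_subsets <- function(catalog, n_per_side = 30, alpha = 0.05,
                          seed = NULL) {
  validate_catalog(catalog)
  assert_scalar_number(n_per_side, "n_per_side", lower = 1)
  assert_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  pos <- catalog[catalog$valence >= 7, ]
  neg <- catalog[catalog$valence <= 2.6, ]
  check_feasible <- function(pos, neg) {
    if (nrow(pos) < n_per_side || nrow(neg) < n_per_side) {
      stop("polar subsets infeasible: arousal window collapsed below ",
           n_per_side, " items per side", call. = FALSE)
    }
  }
  check_feasible(pos, neg)
  window <- range(c(pos$arousal, neg$arousal))
  arousal_p <- function(pos, neg) {
    suppressWarnings(
      wilcox.test(pos$arousal, neg$arousal, alternative = "two.sided",
                  exact = FALSE, correct = TRUE)$p.value
    )
  }
  p <- arousal_p(pos, neg)
  while (p <= alpha) {
    med <- median(c(pos$arousal, neg$arousal))
    window <- c(min(window[1] + 0.1, med), max(window[2] - 0.1, med))
    if (diff(window) < .Machine$double.eps) {
      stop("polar subsets infeasible: arousal window collapsed", call. = FALSE)
    }
    pos <- pos[pos$arousal >= window[1] & pos$arousal <= window[2], ]
    neg <- neg[neg$arousal >= window[1] & neg$arousal <= window[2], ]
    check_feasible(pos, neg)
    p <- arousal_p(pos, neg)
  }
  with_seed(seed, {
    structure(
      list(
        positive = sample(pos$stim_id, n_per_side),
        negative = sample(neg$stim_id, n_per_side),
        arousal_window = window,
        equivalence_p = p
      ),
      class = "polar_subsets"
    )
  })
}

#' @exportS3Method base::print
print.polar_subsets <- function(x, ...) {
  cat(sprintf(
    "<polar_subsets: %d positive / %d negative, arousal window (%.2f, %.2f), p=%.3f>\n",
    length(x$positive), length(x$negative),
    x$arousal_window[1], x$arousal_window[2], x$equivalence_p
  ))
  invisible(x)
}

#' Randomly assign polar-subset stimuli to trial types
#'
#' Splits the pooled polar stimuli uniformly at random into Mod-PS and
#' Mod-FS trials, balanced between positive and negative valence within
#' each trial type.
#'
#' @param subsets A [polar_subsets()] object.
#' @param n_ps,n_fs Number of Mod-PS and Mod-FS trials (defaults 40 and
#'   20); each must be even and `n_ps + n_fs` must not exceed the pooled
#'   subset size.
#' @param seed Integer seed.
#' @return `data.frame` with columns `stim_id`, `trial_type`, `polarity`.
#' @export
assign_trials <- function(subsets, n_ps = 40, n_fs = 20, seed = NULL) {
  stopifnot(inherits(subsets, "polar_subsets"))
  n_side <- length(subsets$positive)
  if (n_ps %% 2 != 0 || n_fs %% 2 != 0) {
    stop("balanced assignment infeasible: n_ps and n_fs must be even",
         call. = FALSE)
  }
  if ((n_ps + n_fs) / 2 > n_side) {
    stop("assignment infeasible: not enough stimuli per side", call. = FALSE)
  }
  with_seed(seed, {
    assign_side <- function(ids, polarity) {
      ids <- sample(ids, (n_ps + n_fs) / 2)
      data.frame(
        stim_id = ids,
        trial_type = rep(c("Mod-PS", "Mod-FS"), c(n_ps / 2, n_fs / 2)),
        polarity = polarity,
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(assign_side(subsets$positive, "positive"),
                 assign_side(subsets$negative, "negative"))
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}
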