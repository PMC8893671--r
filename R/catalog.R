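#' Generate a synthetic normative stimulus catalog
#'
#' Emulates a normative picture-set pool on the 1-9 Likert valence/arousal
#' plane. Valence is drawn from a bimodal mixture (pleasant and unpleasant
#' modes); arousal increases with valence extremity (the classic
#' "boomerang" shape), with the unpleasant limb slightly steeper. The
#' generator guarantees feasibility of downstream polar sampling: at least
#' 30 items with valence >= 7 and at least 30 with valence <= 2.6, each
#' tail containing at least 30 items with arousal strictly inside
#' (4.6, 6.8).
#'
#' @param n Number of stimuli; must be at least 60.
#' @param seed Integer seed for reproducibility.
#' @return A `data.frame` with columns `stim_id` (character, unique),
#'   `valence`, `arousal` (numeric, in `[1, 9]`).
#' @export
generate_stimulus_catalog <- function(n, seed = NULL) {
  assert_scalar_number(n, "n", lower = 1)
  n <- as.integer(n)
  if (n < 60L) stop("catalog infeasible: n must be >= 60", call. = FALSE)
  with_seed(seed, {
    ## guaranteed feasibility cells: 30 items per valence tail whose
    ## arousal is drawn from an identical interior distribution, so the
    ## iterative arousal matching always has a matched core to settle on
    val_core <- c(runif(30, 7, 8.6), runif(30, 1.2, 2.6))
    aro_core <- runif(60, 4.7, 6.7)
    n_free <- n - 60L
    mode_hi <- runif(n_free) < 0.5
    val_free <- pmin(9, pmax(1, ifelse(mode_hi, rnorm(n_free, 7.3, 0.9),
                                       rnorm(n_free, 2.3, 0.9))))
    aro_free <- arousal_given_valence(val_free)
    perm <- sample.int(n)
    data.frame(
      stim_id = sprintf("stim%04d", seq_len(n)),
      valence = c(val_core, val_free)[perm],
      arousal = c(aro_core, aro_free)[perm],
      stringsAsFactors = FALSE
    )
  })
}

## conditional arousal model: baseline 3.1, slope 0.55 on valence extremity,
## unpleasant limb steeper by 0.25 (negative content is more arousing at
## matched extremity), Gaussian scatter 0.7, clipped to the Likert range
arousal_given_valence <- function(valence) {
  extremity <- abs(valence - 5)
  slope <- 0.55 + 0.25 * (valence < 5)
  a <- 3.1 + slope * extremity + rnorm(length(valence), 0, 0.7)
  pmin(9, pmax(1, a))
}

validate_catalog <- function(catalog) {
  req <- c("stim_id", "valence", "arousal")
  if (!is.data.frame(catalog) || !all(req %in% names(catalog))) {
    stop("catalog must be a data.frame with columns stim_id, valence, arousal",
         call. = FALSE)
  }
  if (anyDuplicated(catalog$stim_id)) {
    stop("catalog stim_ids must be unique", call. = FALSE)
  }
  if (any(catalog$valence < 1 | catalog$valence > 9) ||
      any(catalog$arousal < 1 | catalog$arousal > 9)) {
    stop("catalog scores must lie in [1, 9]", call. = FALSE)
  }
  invisible(catalog)
}

#' Read / write a stimulus catalog as TSV
#'
#' @param catalog Catalog `data.frame` (see [generate_stimulus_catalog()]).
#' @param path File path.
#' @return `read_catalog()` returns the catalog `data.frame`;
#'   `write_catalog()` returns `path` invisibly.
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  catalog <- read.delim(path, stringsAsFactors = FALSE)
  catalog$stim_id <- as.character(catalog$stim_id)
  validate_catalog(catalog)
  catalog
}
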