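#' Haufe transform: decoder weights to an encoding (activation) pattern
#'
#' Converts backward-model weights into an interpretable forward-model
#' encoding: `encoding = Cov(features) %*% weights / Var(h)`, where `h`
#' are the decision values of the features under the weights. With this
#' scaling the encoding of a whitened-feature decoder equals its weights.
#'
#' @param weights Voxel weight vector (e.g. `model$weights`).
#' @param features Feature matrix, samples in rows (>= 2 samples).
#' @return Per-voxel encoding vector.
#' @export
haufe_transform <- function(weights, features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 2L) {
    stop("haufe_transform needs at least 2 samples", call. = FALSE)
  }
  if (ncol(features) != length(weights)) {
    stop("dimension mismatch", call. = FALSE)
  }
  h <- drop(features %*% weights)
  v <- var(h)
  if (!is.finite(v) || v < .Machine$double.eps) {
    stop("zero-variance decision values", call. = FALSE)
  }
  Xc <- sweep(features, 2, colMeans(features))
  drop(crossprod(Xc, h - mean(h))) / (nrow(features) - 1) / v
}

#' Group-level mean encoding map
#'
#' @param encodings List of per-subject encoding vectors (common voxel
#'   space) or a matrix with subjects in columns.
#' @return Voxelwise arithmetic mean vector.
#' @export
group_mean_encoding <- function(encodings) {
  if (is.list(encodings)) {
    lens <- vapply(encodings, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("encoding maps must share a common voxel space", call. = FALSE)
    }
    if (length(encodings) < 2L) stop(">= 2 subjects required", call. = FALSE)
    encodings <- do.call(cbind, encodings)
  }
  rowMeans(encodings)
}

#' Permutation null distribution of the group mean encoding
#'
#' For each permutation the labels are shuffled within subject, the
#' classifier refit on the true beta maps, Haufe-transformed, and the
#' per-subject encodings group-averaged. Shuffles that leave a single
#' class are redrawn (bounded retries).
#'
#' @param beta_mats List of per-subject feature matrices (samples x
#'   voxels).
#' @param labels_list List of per-subject label vectors in `{-1, +1}`.
#' @param n_perm Number of permutations (>= 100).
#' @param C Soft-margin penalty passed to the classifier.
#' @param seed Integer seed.
#' @return Matrix with `n_perm` rows and one column per voxel.
#' @export
permutation_null <- function(beta_mats, labels_list, n_perm = 1000, C = 1,
                             seed = NULL) {
  assert_scalar_number(n_perm, "n_perm", lower = 100)
  stopifnot(length(beta_mats) == length(labels_list))
  with_seed(seed, {
    n_vox <- ncol(beta_mats[[1]])
    null <- matrix(NA_real_, n_perm, n_vox)
    for (b in seq_len(n_perm)) {
      enc <- lapply(seq_along(beta_mats), function(s) {
        X <- beta_mats[[s]]
        y <- labels_list[[s]]
        for (try in 1:25) {
          y_perm <- sample(y)
          if (length(unique(y_perm)) > 1L) break
        }
        fit <- train_linear_classifier(X, y_perm, C = C)
        haufe_transform(fit$weights, X)
      })
      null[b, ] <- group_mean_encoding(enc)
    }
    null
  })
}

#' Mask an observed encoding map by its permutation null
#'
#' Per-voxel two-sided p-value with add-one correction:
#' `p = (#{|null| >= |observed|} + 1) / (n_perm + 1)`; voxels with
#' `p < alpha` are retained. A pooled-null variant compares each voxel
#' against the null values of all voxels.
#'
#' @param observed Observed group-mean encoding vector.
#' @param null Null matrix from [permutation_null()].
#' @param alpha Significance level (default 0.05).
#' @param pooled Use the pooled-voxel null rather than per-voxel
#'   (default `FALSE`).
#' @return An `encoding_map`: list with `values`, `p_values`, `mask`,
#'   `alpha`.
#' @export
mask_by_permutation <- function(observed, null, alpha = 0.05,
                                pooled = FALSE) {
  if (!nrow(null)) stop("empty null", call. = FALSE)
  if (ncol(null) != length(observed)) stop("dimension mismatch", call. = FALSE)
  n_perm <- nrow(null)
  if (pooled) {
    pool <- abs(as.vector(null))
    r <- vapply(abs(observed), function(o) sum(pool >= o), numeric(1))
    p <- (r + 1) / (length(pool) + 1)
  } else {
    r <- colSums(sweep(abs(null), 2, abs(observed), ">="))
    p <- (r + 1) / (n_perm + 1)
  }
  structure(
    list(values = observed, p_values = p, mask = p < alpha, alpha = alpha),
    class = "encoding_map"
  )
}

#' @exportS3Method base::print
print.encoding_map <- function(x, ...) {
  cat(sprintf("<encoding_map: %d voxels, %d surviving at alpha=%g>\n",
              length(x$values), sum(x$mask), x$alpha))
  invisible(x)
}

#' Shared variance between two encoding maps
#'
#' Squared Pearson correlation of voxelwise encoding values over all joint
#' voxels, or over the joint surviving mask when restricted.
#'
#' @param map1,map2 `encoding_map` objects (or plain numeric vectors) in a
#'   common voxel space.
#' @param restrict_to_mask Restrict to voxels surviving in both maps
#'   (default `FALSE`; requires `encoding_map` inputs).
#' @return Shared variance R-squared in `[0, 1]`.
#' @export
shared_variance <- function(map1, map2, restrict_to_mask = FALSE) {
  v1 <- if (inherits(map1, "encoding_map")) map1$values else map1
  v2 <- if (inherits(map2, "encoding_map")) map2$values else map2
  if (length(v1) != length(v2)) stop("common voxel space required", call. = FALSE)
  keep <- rep(TRUE, length(v1))
  if (restrict_to_mask) {
    if (!inherits(map1, "encoding_map") || !inherits(map2, "encoding_map")) {
      stop("mask restriction requires encoding_map inputs", call. = FALSE)
    }
    keep <- map1$mask & map2$mask
  }
  if (sum(keep) < 3L) stop("fewer than 3 joint voxels", call. = FALSE)
  cor(v1[keep], v2[keep])^2
}
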