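#' Train a linear max-margin (soft-margin SVM) decoder
#'
#' Fits a linear support vector machine with hinge loss and soft-margin
#' penalty `C` by deterministic dual coordinate descent. Features are
#' standardized per voxel using training statistics, which are folded back
#' into the returned weights so the decision value is a plain affine map
#' of raw features: `h(x) = weights . x + offset`. Only volumes with
#' labels in `{-1, +1}` are used; unlabelled volumes (`0`) are dropped.
#'
#' @param features Numeric matrix, samples in rows, voxels in columns.
#' @param labels Integer labels in `{-1, 0, +1}`, one per row.
#' @param C Soft-margin penalty (default 1).
#' @param standardize Standardize each voxel with training mean/SD
#'   (default `TRUE`).
#' @param dimension Which affect dimension the decoder targets
#'   (`"valence"` or `"arousal"`), recorded in the model.
#' @param tol,max_pass Solver convergence controls.
#' @return An object of class `decoder_model` with fields `weights`,
#'   `offset`, `platt_a`/`platt_b` (NA until [fit_platt()]), `dimension`,
#'   and accuracy diagnostics.
#' @export
train_linear_classifier <- function(features, labels, C = 1,
                                    standardize = TRUE,
                                    dimension = "valence",
                                    tol = 1e-10, max_pass = 5000) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) != length(labels)) {
    stop("one label per feature row required", call. = FALSE)
  }
  if (!all(labels %in% c(-1, 0, 1))) {
    stop("labels must be in {-1, 0, +1}", call. = FALSE)
  }
  keep <- labels != 0
  X <- features[keep, , drop = FALSE]
  y <- as.numeric(labels[keep])
  if (length(unique(y)) < 2L) {
    stop("training requires both classes", call. = FALSE)
  }
  if (standardize) {
    centre <- colMeans(X)
    scale <- apply(X, 2, sd)
    scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  } else {
    centre <- numeric(ncol(X))
    scale <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, centre), 2, scale, "/")
  fit <- .svm_dcd(cbind(Xs, 1), y, C, tol, max_pass)
  w_std <- fit$w[seq_len(ncol(X))]
  b_std <- fit$w[ncol(X) + 1L]
  weights <- w_std / scale
  offset <- b_std - sum(w_std * centre / scale)
  structure(
    list(
      weights = weights,
      offset = offset,
      platt_a = NA_real_,
      platt_b = NA_real_,
      dimension = dimension,
      accuracy_full = NA_real_,
      accuracy_reliable = NA_real_,
      C = C,
      n_train = length(y),
      converged = fit$converged
    ),
    class = "decoder_model"
  )
}

#' @exportS3Method base::print
print.decoder_model <- function(x, ...) {
  cat(sprintf(
    "<decoder_model [%s]: %d voxels, C=%g, Platt %s, acc full=%s reliable=%s>\n",
    x$dimension, length(x$weights), x$C,
    if (is.na(x$platt_a)) "uncalibrated" else "calibrated",
    format(x$accuracy_full, digits = 3),
    format(x$accuracy_reliable, digits = 3)
  ))
  invisible(x)
}

#' Signed hyperplane distance of volumes under a decoder
#'
#' `h = weights . x + offset` (decision value; not normalized by the
#' weight norm).
#'
#' @param model A `decoder_model`.
#' @param x Numeric vector (one volume) or matrix with samples in rows.
#' @return Numeric vector of decision values.
#' @export
hyperplane_distance <- function(model, x) {
  stopifnot(inherits(model, "decoder_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model$weights)) {
    stop("dimension mismatch between volumes and decoder weights",
         call. = FALSE)
  }
  drop(x %*% model$weights) + model$offset
}

#' Platt-scale decision values into class probabilities
#'
#' Fits the logistic calibration `Pr(y = +1 | h) = 1 / (1 + exp(a h + b))`
#' by regularized maximum likelihood with the class-count-smoothed targets
#' of Platt's algorithm (Newton iterations with backtracking). The fitted
#' map is monotone increasing in `h` (`a < 0`) whenever the decision
#' values separate the classes in the usual orientation.
#'
#' @param h Decision values (e.g. from [hyperplane_distance()]).
#' @param y Labels in `{-1, +1}`.
#' @return Named numeric vector `c(platt_a, platt_b)`.
#' @export
fit_platt <- function(h, y) {
  if (length(h) != length(y)) stop("length mismatch", call. = FALSE)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2L) {
    stop("labels must contain both classes in {-1, +1}", call. = FALSE)
  }
  if (sd(h) < .Machine$double.eps) {
    stop("degenerate decision values: constant h", call. = FALSE)
  }
  n_pos <- sum(y == 1)
  n_neg <- sum(y == -1)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  targ <- ifelse(y == 1, t_pos, t_neg)
  obj <- function(A, B) {
    f <- A * h + B
    ## stable log(1 + exp(f)) and cross-entropy with smoothed targets
    sum(ifelse(f >= 0, targ * f + log1p(exp(-f)), (targ - 1) * f + log1p(exp(f))))
  }
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  fval <- obj(A, B)
  sigma <- 1e-12 # Hessian ridge
  for (it in seq_len(100)) {
    f <- A * h + B
    p <- 1 / (1 + exp(f))   # P(y = +1)
    d1 <- targ - (1 - p)    # dF/df
    d2 <- p * (1 - p)
    g_A <- sum(h * d1)
    g_B <- sum(d1)
    if (max(abs(g_A), abs(g_B)) < 1e-10) break
    h_AA <- sum(h * h * d2) + sigma
    h_BB <- sum(d2) + sigma
    h_AB <- sum(h * d2)
    det <- h_AA * h_BB - h_AB^2
    dA <- -(h_BB * g_A - h_AB * g_B) / det
    dB <- -(h_AA * g_B - h_AB * g_A) / det
    step <- 1
    repeat {
      newf <- obj(A + step * dA, B + step * dB)
      if (newf < fval + 1e-4 * step * (g_A * dA + g_B * dB)) {
        A <- A + step * dA
        B <- B + step * dB
        fval <- newf
        break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  c(platt_a = A, platt_b = B)
}

#' Calibrate a decoder's Platt coefficients in place
#'
#' @param model A `decoder_model`.
#' @param features,labels Calibration data (labels in `{-1, 0, +1}`;
#'   unlabelled rows dropped).
#' @return The model with `platt_a`, `platt_b` filled in.
#' @export
calibrate_decoder <- function(model, features, labels) {
  keep <- labels != 0
  h <- hyperplane_distance(model, features[keep, , drop = FALSE])
  ab <- fit_platt(h, as.numeric(labels[keep]))
  model$platt_a <- unname(ab["platt_a"])
  model$platt_b <- unname(ab["platt_b"])
  model
}

#' Decode volumes into positive-class probabilities
#'
#' Applies the Platt map to the hyperplane distance:
#' `Pr = 1 / (1 + exp(a h + b))`.
#'
#' @param model A calibrated `decoder_model`.
#' @param x Volume vector or matrix (samples in rows).
#' @return Probabilities in `[0, 1]`.
#' @export
decode <- function(model, x) {
  stopifnot(inherits(model, "decoder_model"))
  if (is.na(model$platt_a) || is.na(model$platt_b)) {
    stop("decoder is not calibrated; run calibrate_decoder() first",
         call. = FALSE)
  }
  h <- hyperplane_distance(model, x)
  1 / (1 + exp(model$platt_a * h + model$platt_b))
}

#' Held-out classification accuracy with an exact binomial test
#'
#' Proportion of held-out volumes whose decision-value sign matches the
#' label, with the exact one-sided binomial p-value against chance 0.5.
#'
#' @param model A `decoder_model`.
#' @param features,labels Held-out data (labels in `{-1, 0, +1}`).
#' @return List with `accuracy`, `n`, `k` and `p`.
#' @export
within_subject_accuracy <- function(model, features, labels) {
  keep <- labels != 0
  if (!any(keep)) stop("empty held-out set", call. = FALSE)
  h <- hyperplane_distance(model, features[keep, , drop = FALSE])
  y <- as.numeric(labels[keep])
  k <- sum(sign(h) == y)
  n <- length(y)
  list(accuracy = k / n, n = n, k = k,
       p = pbinom(k - 1, n, 0.5, lower.tail = FALSE))
}

#' Cross-validated decoding accuracy
#'
#' Stratified k-fold cross-validation of [train_linear_classifier()];
#' pooled fold predictions are scored against chance with the exact
#' binomial test.
#'
#' @param features,labels Full labelled data set.
#' @param k Number of folds (default 10).
#' @param C Soft-margin penalty.
#' @param seed Integer seed for the fold assignment.
#' @return List with `accuracy`, `n`, `k`, `p` and the per-sample pooled
#'   predictions (`h`).
#' @export
cv_accuracy <- function(features, labels, k = 10, C = 1, seed = NULL) {
  keep <- which(labels != 0)
  X <- features[keep, , drop = FALSE]
  y <- as.numeric(labels[keep])
  n <- length(y)
  k <- min(k, n)
  with_seed(seed, {
    folds <- integer(n)
    for (cls in c(-1, 1)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    h <- numeric(n)
    for (f in seq_len(k)) {
      test <- folds == f
      if (!any(test)) next
      fit <- train_linear_classifier(X[!test, , drop = FALSE], y[!test], C = C)
      h[test] <- hyperplane_distance(fit, X[test, , drop = FALSE])
    }
    correct <- sum(sign(h) == y)
    list(accuracy = correct / n, n = n, k = correct,
         p = pbinom(correct - 1, n, 0.5, lower.tail = FALSE), h = h)
  })
}

#' Serialize a decoder to a portable JSON container
#'
#' @param model A `decoder_model`.
#' @param path File path.
#' @return `read_decoder()` returns the `decoder_model`;
#'   `write_decoder()` returns `path` invisibly.
#' @export
write_decoder <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  payload <- unclass(model)
  payload$format_version <- 1L
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decoder
#' @export
read_decoder <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$format_version <- NULL
  structure(payload, class = "decoder_model")
}
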