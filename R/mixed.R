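#' Fit a linear mixed-effects model and summarize it
#'
#' Thin wrapper around [lme4::lmer()] (maximum likelihood) returning a
#' compact fit summary: fixed-effect Wald t-tests with a residual df
#' approximation (`df = n - p`), random-effect variances, a marginal
#' adjusted R-squared computed on the fixed-effects predictions, and a
#' likelihood-ratio test of the random effects against the fixed-only
#' linear model (null hypothesis: responses generated by fixed effects
#' alone; the boundary-mixture caveat applies, making the test
#' conservative). Formulas without random-effect terms fall back to
#' [stats::lm()].
#'
#' @param formula Model formula, `lme4`-style.
#' @param data Model frame.
#' @return An object of class `affect_fit` with elements `fixed_effects`
#'   (data.frame: estimate, se, t, p), `ranef_variances`, `r2_adj`,
#'   `loglik`, `lrt_p`, `singular`, `n`, and the underlying `model`.
#' @export
fit_mixed <- function(formula, data) {
  data <- stats::model.frame(stats::terms(lme4::subbars(formula)), data)
  has_ranef <- length(lme4::findbars(formula)) > 0
  if (has_ranef) {
    model <- lme4::lmer(formula, data = data, REML = FALSE,
                        control = lme4::lmerControl(
                          optimizer = "bobyqa",
                          optCtrl = list(maxfun = 1e5),
                          check.conv.singular = "ignore"))
    fe <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    vc <- as.data.frame(lme4::VarCorr(model))
    ranef_var <- setNames(
      vc$vcov[is.na(vc$var2)],
      paste(vc$grp[is.na(vc$var2)], vc$var1[is.na(vc$var2)], sep = ":")
    )
    singular <- lme4::isSingular(model)
    X <- lme4::getME(model, "X")
    y <- lme4::getME(model, "y")
    yhat_fixed <- drop(X %*% fe)
    ## LRT against the fixed-effects-only linear model
    lm0 <- lm(y ~ X - 1)
    lrt_stat <- 2 * (as.numeric(logLik(model)) - as.numeric(logLik(lm0)))
    lrt_df <- nrow(vc)
    lrt_p <- pchisq(max(0, lrt_stat), df = lrt_df, lower.tail = FALSE)
  } else {
    model <- lm(formula, data = data)
    fe <- coef(model)
    se <- sqrt(diag(stats::vcov(model)))
    ranef_var <- numeric(0)
    singular <- FALSE
    X <- model.matrix(model)
    y <- model$model[[1]]
    yhat_fixed <- stats::fitted(model)
    lrt_stat <- NA_real_; lrt_df <- NA_integer_; lrt_p <- NA_real_
  }
  n <- length(y)
  p_fix <- length(fe)
  tval <- fe / se
  df_resid <- max(1, n - p_fix)
  pval <- 2 * pt(abs(tval), df = df_resid, lower.tail = FALSE)
  r2 <- if (var(y) > 0 && var(yhat_fixed) > 0) cor(y, yhat_fixed)^2 else 0
  r2_adj <- 1 - (1 - r2) * (n - 1) / max(1, n - p_fix - 1)
  structure(
    list(
      fixed_effects = data.frame(
        term = names(fe), estimate = unname(fe), se = unname(se),
        t = unname(tval), p = unname(pval), stringsAsFactors = FALSE
      ),
      ranef_variances = ranef_var,
      r2_adj = r2_adj,
      loglik = as.numeric(logLik(model)),
      lrt_stat = lrt_stat, lrt_df = lrt_df, lrt_p = lrt_p,
      singular = singular,
      n = n,
      formula = formula,
      model = model
    ),
    class = "affect_fit"
  )
}

#' @exportS3Method base::print
print.affect_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Linear mixed-effects fit (n = %d)\n", x$n))
  cat("  ", deparse(x$formula), "\n", sep = "")
  fe <- x$fixed_effects
  fe[, -1] <- lapply(fe[, -1], signif, digits)
  print(fe, row.names = FALSE)
  if (length(x$ranef_variances)) {
    cat("Random-effect variances:\n")
    print(signif(x$ranef_variances, digits))
  }
  cat(sprintf("R2_adj (marginal) = %.3f; logLik = %.1f; LRT p = %s%s\n",
              x$r2_adj, x$loglik, format.pval(x$lrt_p, digits = 2),
              if (isTRUE(x$singular)) " [singular fit]" else ""))
  invisible(x)
}

## pull one fixed-effect row; errors if missing
fixed_effect <- function(fit, term) {
  row <- fit$fixed_effects[fit$fixed_effects$term == term, ]
  if (!nrow(row)) {
    stop("term '", term, "' not found in fit; have: ",
         paste(fit$fixed_effects$term, collapse = ", "), call. = FALSE)
  }
  row
}

#' Write an `affect_fit` as a structured JSON report
#'
#' @param fit An `affect_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    formula = deparse(fit$formula),
    n = fit$n,
    fixed_effects = fit$fixed_effects,
    ranef_variances = as.list(fit$ranef_variances),
    r2_adj = fit$r2_adj,
    loglik = fit$loglik,
    lrt_p = fit$lrt_p,
    singular = fit$singular
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
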