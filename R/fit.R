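#' Fit one logistic outcome model with full inferential outputs
#'
#' Maximum-likelihood logistic regression of a binary outcome on the
#' specification's predictors, reported the way the tailoring analysis
#' reports it: odds ratios with Wald 95% intervals, per-term p-values with
#' Benjamini-Hochberg significance flags (within the model's predictor
#' family, intercept excluded), the likelihood-ratio test against the
#' intercept-only model, Tjur's coefficient of discrimination, per-column
#' variance inflation factors, type II analysis of deviance, and
#' Tukey-adjusted pairwise contrasts for every factor with three or more
#' levels. Perfect separation and rank deficiency raise errors rather than
#' returning silently unstable estimates.
#'
#' @param data Analysis table (or a `jitai_tables` list, from which the
#'   spec's scope is taken).
#' @param spec A `model_spec`.
#' @param alpha Significance level for the Benjamini-Hochberg flags.
#' @param separation `"error"` (default) raises on detected
#'   (quasi-)separation; `"firth"` refits with Firth's bias-reduced
#'   penalized likelihood (see [firth_logistic()]), which keeps every
#'   estimate finite. Firth fits report coefficients, Wald intervals,
#'   penalized LR vs null, Tjur R2 and VIF, but no type II or Tukey
#'   decompositions.
#' @return Object of class `jitai_fit`: the fitted `glm`, a coefficient
#'   table, and the derived statistics. The `method` element records
#'   whether plain maximum likelihood or the Firth fallback produced the
#'   estimates.
#' @export
fit_model <- function(data, spec, alpha = 0.05,
                      separation = c("error", "firth")) {
  separation <- match.arg(separation)
  stopifnot(inherits(spec, "model_spec"))
  if (inherits(data, "jitai_tables")) data <- data[[spec$scope]]
  missing_cols <- setdiff(c(spec$outcome, spec$predictors), names(data))
  if (length(missing_cols)) {
    stop("columns absent from ", spec$scope, " table: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data[, c(spec$outcome, spec$predictors)]
  if (anyNA(df)) stop("missing values in scoped model columns")
  y <- df[[spec$outcome]]
  if (!all(y %in% c(0, 1, TRUE, FALSE))) stop("outcome must be binary")
  df[[spec$outcome]] <- as.numeric(y)
  for (nm in intersect(names(factor_levels), spec$predictors)) {
    df[[nm]] <- factor(df[[nm]], levels = factor_levels[[nm]])
    df[[nm]] <- droplevels(df[[nm]])
  }
  fml <- as.formula(paste(spec$outcome, "~",
                          paste(spec$predictors, collapse = " + ")))
  model <- suppressWarnings(glm(fml, family = binomial(), data = df))
  cf <- coef(model)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  separated <- any(abs(cf) > 15) ||
    any(model$fitted.values > 1 - 1e-10) ||
    any(model$fitted.values < 1e-10) || !model$converged
  if (separated && separation == "error") {
    if (any(abs(cf) > 15)) {
      stop("(quasi-)separation detected; unstable terms: ",
           paste(names(cf)[abs(cf) > 15], collapse = ", "))
    }
    stop("logistic fit did not converge")
  }

  method <- "ml"
  if (separated) {
    method <- "firth"
    Xfull <- model.matrix(model)
    y <- df[[spec$outcome]]
    ff <- firth_logistic(Xfull, y)
    f0 <- firth_logistic(Xfull[, 1, drop = FALSE], y)
    cf <- ff$coefficients
    se <- sqrt(diag(ff$vcov))
    fitted_p <- ff$fitted
    lr <- list(chi2 = 2 * (ff$loglik - f0$loglik),
               df = length(cf) - 1)
    lr$p <- pchisq(lr$chi2, lr$df, lower.tail = FALSE)
  } else {
    se <- sqrt(diag(vcov(model)))
    fitted_p <- model$fitted.values
    lr <- NULL
  }

  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  ci_lo <- cf - qnorm(0.975) * se
  ci_hi <- cf + qnorm(0.975) * se
  terms_tab <- data.frame(
    term = names(cf), estimate = unname(cf), se = unname(se),
    odds_ratio = exp(unname(cf)),
    ci_low = exp(unname(ci_lo)), ci_high = exp(unname(ci_hi)),
    p_value = unname(p), stringsAsFactors = FALSE)
  non_int <- terms_tab$term != "(Intercept)"
  terms_tab$bh_significant <- NA
  terms_tab$bh_significant[non_int] <-
    bh_adjust(terms_tab$p_value[non_int], alpha)

  X <- model.matrix(model)[, -1, drop = FALSE]
  result <- structure(list(
    model = model, spec = spec, n = nrow(df), method = method,
    terms = terms_tab,
    lr = NULL, tjur_r2 = NULL, vif = NULL,
    type2 = NULL, tukey = NULL
  ), class = "jitai_fit")
  y01 <- df[[spec$outcome]]
  result$lr <- if (method == "ml") lr_test_vs_null(result) else lr
  result$tjur_r2 <- mean(fitted_p[y01 == 1]) - mean(fitted_p[y01 == 0])
  result$vif <- vif_design(X)
  result$tukey <- list()
  if (method == "ml") {
    result$type2 <- type2_anova(result)
    for (nm in intersect(names(factor_levels), spec$predictors)) {
      if (nlevels(df[[nm]]) >= 3) {
        result$tukey[[nm]] <- tukey_pairwise(result, nm)
      }
    }
  }
  result
}

#' Firth's bias-reduced logistic regression
#'
#' Penalized maximum likelihood with Jeffreys-prior penalty
#' `0.5 * log det I(beta)`, fitted by the standard modified-score
#' iteration. Estimates stay finite under complete or quasi-complete
#' separation, which is why [fit_model()] offers it as its separation
#' fallback.
#'
#' @param X Design matrix including the intercept column.
#' @param y Binary response (0/1).
#' @param maxit,tol Iteration controls.
#' @return List with `coefficients`, `vcov` (inverse penalized
#'   information), `fitted`, `loglik` (penalized), `iter`, `converged`.
#' @export
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  beta <- rep(0, ncol(X))
  delta <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    inv <- solve(XtWX)
    h <- w * rowSums((X %*% inv) * X)
    score <- crossprod(X, y - mu + h * (0.5 - mu))
    delta <- drop(inv %*% score)
    # step-halving keeps the iteration stable far from the optimum
    while (max(abs(delta)) > 5) delta <- delta / 2
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  XtWX <- crossprod(X, X * w)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu)) +
    0.5 * determinant(XtWX, logarithm = TRUE)$modulus
  list(coefficients = setNames(beta, colnames(X)),
       vcov = solve(XtWX), fitted = mu,
       loglik = as.numeric(ll), iter = it,
       converged = max(abs(delta)) < tol)
}

#' Likelihood-ratio test against the intercept-only model
#'
#' Analysis of deviance of the fitted model versus the null model on the
#' same rows: the statistic is the deviance difference, the degrees of
#' freedom the number of non-intercept parameters.
#'
#' @param result A `jitai_fit` (or bare `glm`).
#' @return List with `chi2`, `df`, `p`.
#' @export
lr_test_vs_null <- function(result) {
  model <- if (inherits(result, "jitai_fit")) result$model else result
  chi2 <- model$null.deviance - model$deviance
  df <- model$df.null - model$df.residual
  list(chi2 = chi2, df = df,
       p = if (df == 0) NA_real_ else pchisq(chi2, df, lower.tail = FALSE))
}

#' Tjur's coefficient of discrimination
#'
#' Mean fitted probability among events minus the mean among non-events.
#'
#' @param result A `jitai_fit` or fitted binomial `glm`.
#' @return Numeric in \[-1, 1\].
#' @export
tjur_r2 <- function(result) {
  model <- if (inherits(result, "jitai_fit")) result$model else result
  y <- model$y
  if (all(y == 1) || all(y == 0)) {
    stop("Tjur R2 undefined: outcome has a single class")
  }
  fitted <- model$fitted.values
  mean(fitted[y == 1]) - mean(fitted[y == 0])
}

#' Benjamini-Hochberg significance flags
#'
#' Standard step-up false-discovery-rate procedure over a family of
#' p-values; returns which hypotheses are rejected at the given level.
#' Flags are monotone: rejecting a p-value implies rejecting all smaller
#' ones.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param alpha Significance level.
#' @return Logical vector of rejection flags, in the input order.
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH") <= alpha
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing column `j` on
#' the remaining columns (with intercept). Exactly collinear columns are
#' reported as `Inf`.
#'
#' @param X Numeric design matrix, intercept column excluded.
#' @return Named numeric vector of VIFs.
#' @export
vif_design <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) return(setNames(rep(1, p), colnames(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    yj <- X[, j]
    Zj <- cbind(1, X[, -j, drop = FALSE])
    fit <- lm.fit(Zj, yj)
    ssr <- sum(fit$residuals^2)
    sst <- sum((yj - mean(yj))^2)
    if (sst == 0) { out[j] <- Inf; next }
    r2 <- 1 - ssr / sst
    out[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  names(out) <- colnames(X)
  if (any(is.infinite(out))) {
    warning("exactly collinear design column(s): ",
            paste(names(out)[is.infinite(out)], collapse = ", "))
  }
  out
}

#' Type II analysis of deviance
#'
#' For each model term, a likelihood-ratio test of the model with that term
#' dropped (all columns of a multi-level factor at once) against the full
#' model, computed with `car::Anova(type = 2)`.
#'
#' @param result A `jitai_fit` or fitted `glm`.
#' @return Data frame with one row per term: `term`, `chi2`, `df`, `p`.
#' @export
type2_anova <- function(result) {
  model <- if (inherits(result, "jitai_fit")) result$model else result
  a <- car::Anova(model, type = 2, test.statistic = "LR")
  data.frame(term = rownames(a), chi2 = a[["LR Chisq"]], df = a[["Df"]],
             p = a[["Pr(>Chisq)"]], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Tukey-adjusted pairwise contrasts for a multi-level factor
#'
#' All level-pair contrasts of a factor with three or more levels, on the
#' log-odds scale, with family-wise adjusted p-values from the
#' multivariate-normal (single-step) method on the model contrasts.
#'
#' @param result A `jitai_fit`.
#' @param factor_name Name of a factor predictor with >= 3 levels.
#' @return Data frame with `contrast`, `estimate`, `se`, `p_adjusted`,
#'   `p_unadjusted`.
#' @export
tukey_pairwise <- function(result, factor_name) {
  model <- if (inherits(result, "jitai_fit")) result$model else result
  fac <- model$model[[factor_name]]
  if (is.null(fac) || !is.factor(fac)) {
    stop("'", factor_name, "' is not a factor in the model")
  }
  if (nlevels(fac) < 3) {
    stop("factor '", factor_name,
         "' has fewer than 3 levels; use the Wald test for 2-level factors")
  }
  linfct <- do.call(multcomp::mcp,
                    setNames(list("Tukey"), factor_name))
  gl <- multcomp::glht(model, linfct = linfct)
  sm <- summary(gl)
  raw <- summary(gl, test = multcomp::adjusted("none"))
  data.frame(
    contrast = names(sm$test$coefficients),
    estimate = unname(sm$test$coefficients),
    se = unname(sm$test$sigma),
    p_adjusted = unname(sm$test$pvalues),
    p_unadjusted = unname(raw$test$pvalues),
    stringsAsFactors = FALSE)
}

#' @export
print.jitai_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic model of '%s' on the %s table (n = %d)\n",
              x$spec$outcome, x$spec$scope, x$n))
  cat(sprintf("LR vs null: chi2(%d) = %.1f, p %s; Tjur R2 = %.3f\n",
              x$lr$df, x$lr$chi2,
              format.pval(x$lr$p, digits = 2), x$tjur_r2))
  tab <- x$terms
  tab$odds_ratio <- round(tab$odds_ratio, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p_value <- signif(tab$p_value, 2)
  print(tab[, c("term", "odds_ratio", "ci_low", "ci_high", "p_value",
                "bh_significant")], row.names = FALSE)
  invisible(x)
}
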