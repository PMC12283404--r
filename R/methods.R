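# S3 methods for range_fit, range_effect and multi_tree_summary.

#' @export
print.range_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<range_fit: %s>  n = %d, residual df = %d\n",
              x$model, x$n_obs, x$residual_df))
  print(round(rbind(estimate = x$beta, se = x$se), digits))
  if (!is.na(x$lambda_hat))
    cat(sprintf("Pagel's lambda (ML): %.4f\n", x$lambda_hat))
  if (!is.na(x$dispersion_phi))
    cat(sprintf("dispersion phi: %.4f\n", x$dispersion_phi))
  if (!is.na(x$loglik))
    cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' @export
summary.range_fit <- function(object, ...) {
  est <- object$beta; se <- object$se
  stat <- est / se
  # t reference for Gaussian models, normal for quasi-likelihood
  if (object$model %in% c("gls", "pgls", "ols_log")) {
    p <- 2 * stats::pt(abs(stat), df = object$residual_df, lower.tail = FALSE)
    statname <- "t value"
  } else {
    p <- 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
    statname <- "z value"
  }
  tab <- cbind(Estimate = est, `Std. Error` = se, stat = stat, `Pr(>|stat|)` = p)
  colnames(tab)[3] <- statname
  out <- list(model = object$model, coefficients = tab,
              lambda_hat = object$lambda_hat,
              dispersion_phi = object$dispersion_phi,
              loglik = object$loglik, n_obs = object$n_obs,
              residual_df = object$residual_df,
              sigma = sqrt(object$sigma2_reml))
  class(out) <- "summary.range_fit"
  out
}

#' @export
print.summary.range_fit <- function(x, ...) {
  cat(sprintf("Model: %s (n = %d)\n\nCoefficients:\n", x$model, x$n_obs))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (!is.na(x$lambda_hat))
    cat(sprintf("\nPagel's lambda (ML): %.4f\n", x$lambda_hat))
  if (!is.na(x$dispersion_phi))
    cat(sprintf("\ndispersion phi: %.4f\n", x$dispersion_phi))
  invisible(x)
}

#' @export
coef.range_fit <- function(object, ...) object$beta

#' @export
vcov.range_fit <- function(object, ...) object$vcov

#' @export
logLik.range_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 1 +
              as.integer(!is.na(object$lambda_hat)),
            nobs = object$n_obs, class = "logLik")
}

#' @export
residuals.range_fit <- function(object, ...) object$residuals

#' @export
fitted.range_fit <- function(object, ...) object$fitted

#' Predict from a range-size regression
#'
#' For fits built through [fit_range_model()], `newdata` is passed through
#' the stored model terms; otherwise a design matrix `newX` is multiplied
#' directly. Predictions are on the linear-predictor scale (log scale for
#' `ols_log`, `pgls` and `quasipoisson`); set `type = "response"` to
#' exponentiate.
#'
#' @param object A `range_fit`.
#' @param newdata Data frame (formula fits) or `NULL`.
#' @param newX Design matrix (matrix-interface fits).
#' @param type `"link"` or `"response"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.range_fit <- function(object, newdata = NULL, newX = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (!is.null(newdata)) {
    .assert(!is.null(object$terms), "fit has no stored terms; supply newX")
    X <- stats::model.matrix(stats::delete.response(object$terms), newdata)
  } else if (!is.null(newX)) {
    X <- as.matrix(newX)
  } else {
    X <- object$X
  }
  eta <- as.numeric(X %*% object$beta)
  if (type == "response" &&
      object$model %in% c("ols_log", "pgls", "quasipoisson")) exp(eta) else eta
}

#' Simulate responses from a fitted phylogenetic regression
#'
#' For `pgls` fits, draws multivariate-normal responses with mean `X beta`
#' and covariance `sigma2 * lambda_transform(C, lambda_hat)` on the fit's
#' own tree (parametric bootstrap). For `ols_log`/`gls` fits, draws
#' independent Gaussian residuals.
#'
#' @param object A `range_fit`.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A matrix with `nsim` columns.
#' @export
simulate.range_fit <- function(object, nsim = 1, seed = NULL, ...) {
  .set_seed_if(seed)
  n <- object$n_obs
  mu <- object$fitted
  if (object$model == "pgls") {
    C <- phylo_vcv(object$tree, object$taxa)
    V <- object$sigma2_ml * lambda_transform(C, object$lambda_hat)
    L <- t(chol(V))
    out <- mu + L %*% matrix(stats::rnorm(n * nsim), n, nsim)
  } else if (object$model %in% c("gls", "ols_log")) {
    out <- mu + sqrt(object$sigma2_ml) * matrix(stats::rnorm(n * nsim), n, nsim)
  } else {
    stop("simulate() not defined for model ", object$model, call. = FALSE)
  }
  out
}

#' Plot a fitted range-size regression
#'
#' For `pgls` fits, draws the profile log-likelihood of Pagel's lambda with
#' the ML estimate marked; for other models, residuals against fitted
#' values.
#'
#' @param x A `range_fit`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.range_fit <- function(x, ...) {
  if (x$model == "pgls") {
    C <- phylo_vcv(x$tree, x$taxa)
    y <- x$fitted + x$residuals
    lams <- seq(0, 1, length.out = 41)
    ll <- vapply(lams, function(l)
      gls_fit(y, x$X, lambda_transform(C, l))$loglik, numeric(1))
    graphics::plot(lams, ll, type = "l", xlab = expression(lambda),
                   ylab = "profile log-likelihood", ...)
    graphics::abline(v = x$lambda_hat, lty = 2)
  } else {
    graphics::plot(x$fitted, x$residuals, xlab = "fitted",
                   ylab = "residuals", ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' @export
confint.range_fit <- function(object, parm = seq_along(object$beta),
                              level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- object$beta[parm] - z * object$se[parm]
  hi <- object$beta[parm] + z * object$se[parm]
  out <- cbind(lo, hi)
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' @export
print.range_effect <- function(x, ...) {
  cat(sprintf("%s [%s]: %+.1f%% (95%% CI %+.1f%%, %+.1f%%)\n",
              x$coef_name, x$model, x$percent, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
print.multi_tree_summary <- function(x, ...) {
  cat(sprintf("<multi_tree_summary: %s over %d trees>\n", x$model, x$n_trees))
  print(x$coef, row.names = FALSE)
  if (!all(is.na(x$lambda)))
    cat(sprintf("lambda: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$lambda), min(x$lambda), max(x$lambda)))
  invisible(x)
}
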