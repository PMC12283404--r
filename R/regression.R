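# The regression layer: generalized least squares under an arbitrary
# covariance, Pagel's-lambda PGLS by profile maximum likelihood, log-scale
# OLS, and a quasi-Poisson GLM fitted by IRLS. All fitters return a classed
# S3 object `range_fit`; methods live in methods.R.

#' @noRd
.new_range_fit <- function(model, beta, se, sigma2_ml = NA_real_,
                           sigma2_reml = NA_real_, loglik = NA_real_,
                           n_obs, residual_df, lambda_hat = NA_real_,
                           dispersion_phi = NA_real_, fitted, residuals,
                           vcov, X = NULL, tree = NULL, taxa = NULL,
                           call = sys.call(-1)) {
  .assert(length(beta) == length(se), "beta/se length mismatch")
  .assert(n_obs > length(beta), "need more observations than coefficients")
  structure(list(model = model, beta = beta, se = se,
                 sigma2_ml = sigma2_ml, sigma2_reml = sigma2_reml,
                 loglik = loglik, n_obs = n_obs, residual_df = residual_df,
                 lambda_hat = lambda_hat, dispersion_phi = dispersion_phi,
                 fitted = fitted, residuals = residuals, vcov = vcov,
                 X = X, tree = tree, taxa = taxa, call = call),
            class = "range_fit")
}

#' Generalized least squares with a known covariance matrix
#'
#' Solves the GLS normal equations `beta = (X' V^-1 X)^-1 X' V^-1 y` through
#' a Cholesky factorization of `V` (never an explicit inverse): the data are
#' whitened by the factor and an ordinary QR least-squares solve is applied.
#' The error variance is estimated two ways: the maximum-likelihood
#' `e' V^-1 e / n` enters the reported log-likelihood, while standard errors
#' use the REML-consistent `e' V^-1 e / (n - p)` times the unscaled
#' coefficient covariance.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (full column rank).
#' @param V Positive-definite covariance matrix (up to scale).
#' @return A `range_fit` object (`model = "gls"`).
#' @export
gls_fit <- function(y, X, V) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- length(y); p <- ncol(X)
  .assert(nrow(X) == n && nrow(V) == n && ncol(V) == n,
          "dimension mismatch among y, X, V")
  .assert(all(is.finite(y)), "non-finite response values")
  U <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix V is not positive definite (",
         conditionMessage(e), ")", call. = FALSE))
  # whiten: V = U'U  =>  solve(t(U)) %*% . has identity covariance
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qrX <- qr(Xw)
  .assert(qrX$rank == p, "design matrix X is rank-deficient (rank %d < %d)",
          qrX$rank, p)
  beta <- qr.coef(qrX, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  sigma2_ml <- rss / n
  sigma2_reml <- rss / (n - p)
  logdetV <- 2 * sum(log(diag(U)))
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  XtX_inv <- chol2inv(qr.R(qrX))
  vc <- sigma2_reml * XtX_inv
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("b", seq_len(p) - 1L)
  dimnames(vc) <- list(cn, cn)
  fitted <- as.numeric(X %*% beta)
  .new_range_fit(model = "gls",
                 beta = stats::setNames(as.numeric(beta), cn),
                 se = stats::setNames(sqrt(diag(vc)), cn),
                 sigma2_ml = sigma2_ml, sigma2_reml = sigma2_reml,
                 loglik = loglik, n_obs = n, residual_df = n - p,
                 fitted = fitted, residuals = y - fitted, vcov = vc, X = X)
}

#' Phylogenetic GLS with Pagel's lambda by profile maximum likelihood
#'
#' Fits a PGLS regression in which the residual covariance is the Brownian
#' phylogenetic covariance with its off-diagonal entries scaled by Pagel's
#' lambda. The profile log-likelihood over lambda is maximized on `[0, 1]`
#' by bounded scalar optimization (Brent, tolerance 1e-6), with both
#' endpoints evaluated explicitly so that boundary optima are exact. At the
#' optimum the full GLS fit is returned with `lambda_hat` set.
#'
#' @param y Response vector, aligned with `taxa`.
#' @param X Design matrix, rows aligned with `taxa`.
#' @param tree A `phylo` tree containing all `taxa` as tips.
#' @param taxa Character vector of species names aligned with `y`/`X`.
#' @return A `range_fit` object (`model = "pgls"`).
#' @export
pgls_ml <- function(y, X, tree, taxa) {
  .assert(all(is.finite(y)), "non-finite response values")
  C <- phylo_vcv(tree, taxa)
  .assert(all(diag(C) > 0),
          "zero root-to-tip depth: phylogenetic covariance is degenerate")
  profile <- function(lam) {
    fit <- gls_fit(y, X, lambda_transform(C, lam))
    fit$loglik
  }
  opt <- stats::optimize(profile, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  ll <- c(profile(0), opt$objective, profile(1))
  .assert(all(is.finite(ll)), "non-finite profile likelihood")
  lam_hat <- cand[which.max(ll)]
  fit <- gls_fit(y, X, lambda_transform(C, lam_hat))
  fit$model <- "pgls"
  fit$lambda_hat <- lam_hat
  fit$tree <- tree
  fit$taxa <- taxa
  fit$call <- sys.call()
  fit
}

#' Ordinary least squares on the natural-log scale
#'
#' Log-transforms a strictly positive response (specimen count or EOO) and
#' fits OLS with classical standard errors on `n - p` residual degrees of
#' freedom. Natural logs are used throughout so coefficients feed directly
#' into the exp-based percentage-difference effect size.
#'
#' @param y_raw Strictly positive response vector (untransformed).
#' @param X Design matrix.
#' @return A `range_fit` object (`model = "ols_log"`).
#' @export
ols_log <- function(y_raw, X) {
  bad <- which(!(is.finite(y_raw) & y_raw > 0))
  .assert(length(bad) == 0,
          "ols_log requires strictly positive responses; offending indices: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  fit <- gls_fit(log(y_raw), X, diag(length(y_raw)))
  fit$model <- "ols_log"
  fit$call <- sys.call()
  fit
}

#' Quasi-Poisson regression by iteratively reweighted least squares
#'
#' Log-link Poisson score equations solved by IRLS to relative coefficient
#' tolerance 1e-10 (at most 100 iterations). The dispersion is the Pearson
#' statistic over residual degrees of freedom,
#' `phi = sum((y - mu)^2 / mu) / (n - p)`, and standard errors are the
#' Poisson ones inflated by `sqrt(phi)`. Used for the botanical-countries
#' metric, whose prevalence of single-country species leaves counts
#' overdispersed and untransformable to normality.
#'
#' @param y_counts Non-negative integer response (at least one positive).
#' @param X Design matrix.
#' @return A `range_fit` object (`model = "quasipoisson"`), with a
#'   `phi_zero` warning if the fit is exactly degenerate (zero dispersion).
#' @export
quasipoisson_glm <- function(y_counts, X) {
  X <- as.matrix(X); y <- as.numeric(y_counts)
  n <- length(y); p <- ncol(X)
  .assert(all(is.finite(y) & y >= 0 & y == round(y)),
          "y_counts must be non-negative integers")
  .assert(any(y > 0), "all counts are zero; model undefined")
  eta <- log(pmax(y, 0.5))
  beta <- qr.coef(qr(X), eta)
  trace <- numeric(0)
  for (iter in seq_len(100)) {
    eta <- as.numeric(X %*% beta)
    if (any(abs(eta) > 40)) {
      stop("quasipoisson_glm: diverging linear predictor (infinite estimate; ",
           "check for a group with all-zero counts)", call. = FALSE)
    }
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    w <- mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) {
      stop("quasipoisson_glm: diverging linear predictor (infinite estimate; ",
           "check for a group with all-zero counts)", call. = FALSE)
    }
    delta <- max(abs(beta_new - beta)) / max(1, max(abs(beta_new)))
    trace <- c(trace, delta)
    beta <- beta_new
    if (delta < 1e-10) break
    if (iter == 100) {
      stop("quasipoisson_glm failed to converge in 100 iterations; ",
           "relative-change trace tail: ",
           paste(signif(utils::tail(trace, 5), 3), collapse = ", "),
           call. = FALSE)
    }
  }
  eta <- as.numeric(X %*% beta)
  mu <- exp(eta)
  phi <- sum((y - mu)^2 / mu) / (n - p)
  if (phi == 0) {
    warning("quasipoisson_glm: zero dispersion (all residuals exactly zero)",
            call. = FALSE)
  }
  XtWX <- crossprod(X * sqrt(mu))
  info_inv <- chol2inv(chol(XtWX))
  vc <- phi * info_inv
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("b", seq_len(p) - 1L)
  dimnames(vc) <- list(cn, cn)
  .new_range_fit(model = "quasipoisson",
                 beta = stats::setNames(as.numeric(beta), cn),
                 se = stats::setNames(sqrt(pmax(diag(vc), 0)), cn),
                 loglik = NA_real_, n_obs = n, residual_df = n - p,
                 dispersion_phi = phi, fitted = mu,
                 residuals = (y - mu) / sqrt(mu), vcov = vc, X = X,
                 call = sys.call())
}

#' Fit a range-size regression from a formula
#'
#' Formula front-end over the workhorse fitters. The response enters on its
#' natural scale: `ols_log` and `pgls` log-transform it internally (it must
#' be strictly positive), `quasipoisson` treats it as a count.
#'
#' @param formula Model formula, e.g. `eoo_km2 ~ lifeform`.
#' @param data Data frame; for `pgls` it must contain a species column
#'   matching tree tip labels.
#' @param model One of `"ols_log"`, `"quasipoisson"`, `"pgls"`.
#' @param tree A `phylo` tree (required for `pgls`).
#' @param species Name of the species column in `data` (default
#'   `"species"`).
#' @return A `range_fit` with the model terms stored for [predict.range_fit()].
#' @export
fit_range_model <- function(formula, data,
                            model = c("ols_log", "quasipoisson", "pgls"),
                            tree = NULL, species = "species") {
  model <- match.arg(model)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- switch(model,
    ols_log = ols_log(y, X),
    quasipoisson = quasipoisson_glm(y, X),
    pgls = {
      rows <- match(rownames(mf), rownames(data))
      sp <- data[[species]][rows]
      .assert(!is.null(sp), "pgls needs a '%s' column in data", species)
      tip <- match_tips(sp, tree$tip.label)
      .assert(!anyNA(tip), "species not in tree: %s",
              paste(utils::head(sp[is.na(tip)], 5), collapse = ", "))
      bad <- which(!(is.finite(y) & y > 0))
      .assert(length(bad) == 0,
              "pgls log response requires positive values; offenders: %s",
              paste(utils::head(sp[bad], 5), collapse = ", "))
      pgls_ml(log(y), X, tree, tree$tip.label[tip])
    })
  fit$terms <- attr(mf, "terms")
  fit$call <- sys.call()
  fit
}

#' Percentage-difference effect size with 95% confidence interval
#'
#' Transforms a log-scale (or log-link) coefficient into the percentage
#' difference relative to the reference level, `100 * (exp(beta) - 1)`, with
#' Wald 95% limits `100 * (exp(beta -/+ 1.959964 * se) - 1)`. This is the
#' reporting convention for lifeform effects: a value of -58 means the focal
#' group has 58% fewer specimens (or smaller EOO) than the reference group.
#'
#' @param fit A `range_fit` from a log-response or log-link model.
#' @param k Coefficient index or name (default: the second coefficient, the
#'   first predictor after the intercept).
#' @return Object of class `range_effect`: list with `percent`, `ci_low`,
#'   `ci_high`, `beta`, `se`, `coef_name`.
#' @export
effect_size_percent <- function(fit, k = 2L) {
  stopifnot(inherits(fit, "range_fit"))
  if (is.character(k)) k <- match(k, names(fit$beta))
  .assert(!is.na(k) && k >= 1 && k <= length(fit$beta),
          "coefficient index out of range")
  z <- 1.959964
  b <- fit$beta[[k]]; s <- fit$se[[k]]
  structure(list(percent = 100 * (exp(b) - 1),
                 ci_low = 100 * (exp(b - z * s) - 1),
                 ci_high = 100 * (exp(b + z * s) - 1),
                 beta = b, se = s,
                 coef_name = names(fit$beta)[k],
                 model = fit$model),
            class = "range_effect")
}

#' Aggregate regression fits across a set of phylogenetic trees
#'
#' Summarizes tree-wise coefficient estimates by their mean and spread (the
#' standard deviation of the tree-wise estimates, a between-tree
#' uncertainty), retaining the per-tree Pagel's-lambda sequence. All fits
#' must share the model type and design.
#'
#' @param fits List of `range_fit` objects, one per tree.
#' @return Object of class `multi_tree_summary`: coefficient table with
#'   `mean`, `spread`, mean within-fit `se`, plus matrices of the tree-wise
#'   estimates and the lambda sequence.
#' @export
aggregate_trees <- function(fits) {
  .assert(length(fits) >= 1, "no fits to aggregate")
  lapply(fits, function(f) stopifnot(inherits(f, "range_fit")))
  models <- unique(vapply(fits, function(f) f$model, character(1)))
  .assert(length(models) == 1, "fits mix models: %s",
          paste(models, collapse = ", "))
  cn <- names(fits[[1]]$beta)
  same <- vapply(fits, function(f) identical(names(f$beta), cn), logical(1))
  .assert(all(same), "fits have heterogeneous designs")
  B <- do.call(rbind, lapply(fits, function(f) f$beta))
  S <- do.call(rbind, lapply(fits, function(f) f$se))
  spread <- if (nrow(B) > 1) apply(B, 2, stats::sd) else
    stats::setNames(rep(0, ncol(B)), cn)
  structure(list(model = models,
                 n_trees = length(fits),
                 coef = data.frame(coef = cn,
                                   mean = colMeans(B),
                                   spread = spread,
                                   mean_se = colMeans(S),
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
                 estimates = B,
                 lambda = vapply(fits, function(f) f$lambda_hat, numeric(1))),
            class = "multi_tree_summary")
}
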