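# The regression layer: phylogenetic covariance, lambda transform, GLS,
# profile-ML PGLS, log-OLS, quasi-Poisson IRLS, effect sizes, multi-tree
# aggregation.

test_that("phylo_vcv reads path lengths off small trees", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_vcv(tr, c("A", "B", "C"))
  expect_equal(unname(C), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(phylo_vcv(star)), diag(4))
  expect_error(phylo_vcv(tr, c("A", "Z")), "Z")
})

test_that("phylo_vcv matches brute-force MRCA and ape on random trees", {
  for (s in 1:5) {
    tr <- simulate_tree(50, 1, seed = s)
    C <- phylo_vcv(tr)
    expect_equal(C, vcv_bruteforce(tr), tolerance = 1e-12)
    expect_equal(C, ape::vcv(tr)[rownames(C), colnames(C)],
                 tolerance = 1e-12)
    # taxa subsetting and ordering respected
    sub <- sample(tr$tip.label, 10)
    expect_equal(phylo_vcv(tr, sub), C[sub, sub])
  }
})

test_that("lambda transform scales off-diagonals only and checks bounds", {
  C <- rbind(c(2, 1), c(1, 2))
  expect_equal(lambda_transform(C, 0.5), rbind(c(2, 0.5), c(0.5, 2)))
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(c(2, 2)))
  expect_error(lambda_transform(C, 1.2), "lambda")
  expect_error(lambda_transform(C, -0.1), "lambda")
})

test_that("GLS with identity covariance is OLS; 3x3 case matches a direct solve", {
  set.seed(10)
  X <- cbind(1, rnorm(30)); y <- rnorm(30)
  f <- gls_fit(y, X, diag(30))
  lmfit <- lm(y ~ X[, 2])
  expect_equal(unname(f$beta), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(f$se), unname(summary(lmfit)$coefficients[, 2]),
               tolerance = 1e-10)

  V <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))
  y3 <- c(1, 2, 3); X3 <- matrix(1, 3, 1)
  f3 <- gls_fit(y3, X3, V)
  o3 <- gls_bruteforce(y3, X3, V)
  expect_equal(unname(f3$beta), o3$beta, tolerance = 1e-10)
  expect_equal(f3$loglik, o3$loglik, tolerance = 1e-10)
})

test_that("GLS is stable under near-perfect duplication of an observation", {
  set.seed(11)
  n <- 20
  X <- cbind(1, rnorm(n)); y <- as.numeric(X %*% c(1, 2) + rnorm(n))
  base <- gls_fit(y, X, diag(n))
  eps <- 1e-6
  # duplicate observation 1 with covariance 1 - eps to the original
  V <- diag(n + 1); V[1, n + 1] <- V[n + 1, 1] <- 1 - eps
  f <- gls_fit(c(y, y[1]), rbind(X, X[1, ]), V)
  expect_lt(max(abs(f$beta - base$beta)), 1e-3)
})

test_that("GLS rejects singular covariances and rank-deficient designs", {
  X <- cbind(1, c(1, 2, 3))
  expect_error(gls_fit(1:3, X, matrix(1, 3, 3)), "positive definite")
  expect_error(gls_fit(1:3, cbind(X, X[, 2]), diag(3)), "rank")
})

test_that("profile likelihood at lambda_hat dominates a grid", {
  tr <- simulate_tree(60, 1, seed = 13)
  lab <- simulate_lifeform(tr, seed = 14)
  y <- as.numeric(simulate_log_range(tr, lab, 5, 0.4, 0.6, 1, seed = 15))
  X <- cbind(1, as.numeric(lab[tr$tip.label] == "epiphyte"))
  fit <- pgls_ml(y, X, tr, tr$tip.label)
  C <- phylo_vcv(tr)
  grid <- seq(0, 1, length.out = 101)
  ll <- vapply(grid, function(l)
    gls_fit(y, X, lambda_transform(C, l))$loglik, numeric(1))
  expect_gte(fit$loglik, max(ll) - 1e-8)
})

test_that("lambda estimation separates independent from Brownian noise", {
  hits0 <- 0; hits1 <- 0
  nrep <- 15
  for (r in 1:nrep) {
    tr <- simulate_tree(150, 1, seed = 300 + r)
    lab <- simulate_lifeform(tr, seed = 400 + r)
    X <- cbind(1, as.numeric(lab[tr$tip.label] == "epiphyte"))
    y0 <- as.numeric(simulate_log_range(tr, lab, 5, 0.4, 0, 1,
                                        seed = 500 + r))
    y1 <- as.numeric(simulate_log_range(tr, lab, 5, 0.4, 1, 1,
                                        seed = 600 + r))
    if (pgls_ml(y0, X, tr, tr$tip.label)$lambda_hat < 0.1) hits0 <- hits0 + 1
    if (pgls_ml(y1, X, tr, tr$tip.label)$lambda_hat > 0.85) hits1 <- hits1 + 1
  }
  expect_gte(hits0, ceiling(0.9 * nrep))
  expect_gte(hits1, ceiling(0.9 * nrep))
})

test_that("permuting taxa leaves the PGLS fit unchanged", {
  tr <- simulate_tree(40, 1, seed = 17)
  lab <- simulate_lifeform(tr, seed = 18)
  y <- simulate_log_range(tr, lab, 5, 0.4, 0.7, 1, seed = 19)
  X <- cbind(1, as.numeric(lab[tr$tip.label] == "epiphyte"))
  f1 <- pgls_ml(as.numeric(y), X, tr, tr$tip.label)
  perm <- sample(length(tr$tip.label))
  f2 <- pgls_ml(as.numeric(y)[perm], X[perm, ], tr, tr$tip.label[perm])
  expect_equal(f1$beta, f2$beta, tolerance = 1e-7)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
})

test_that("PGLS agrees with nlme::gls + corPagel on one dataset", {
  tr <- simulate_tree(80, 1, seed = 23)
  lab <- simulate_lifeform(tr, seed = 24)
  y <- as.numeric(simulate_log_range(tr, lab, 5, 0.4, 0.6, 1, seed = 25))
  X <- cbind(1, as.numeric(lab[tr$tip.label] == "epiphyte"))
  fit <- pgls_ml(y, X, tr, tr$tip.label)
  d <- data.frame(y = y, x = X[, 2])
  rownames(d) <- tr$tip.label
  # data rows are deliberately in tip order; silence the ordering notice
  ref <- suppressWarnings(
    nlme::gls(y ~ x, data = d, method = "ML",
              correlation = ape::corPagel(0.5, phy = tr)))
  lam_ref <- as.numeric(coef(ref$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(fit$lambda_hat, lam_ref, tolerance = 1e-3)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
})

test_that("log-OLS recovers group geometric means and exact fits", {
  g0 <- c(2, 8); g1 <- c(3, 27)   # geometric means 4 and 9
  X <- cbind(1, c(0, 0, 1, 1))
  f <- ols_log(c(g0, g1), X)
  expect_equal(unname(f$beta), c(log(4), log(9 / 4)), tolerance = 1e-12)

  set.seed(26)
  Xr <- cbind(1, rnorm(15))
  yr <- exp(as.numeric(Xr %*% c(0.5, 1.2)))
  fr <- ols_log(yr, Xr)
  expect_equal(unname(fr$beta), c(0.5, 1.2), tolerance = 1e-10)
  expect_lt(fr$sigma2_ml, 1e-20)
  expect_error(ols_log(c(1, -2, 3), cbind(1, 1:3)), "positive")
})

test_that("log-OLS estimate falls within 3 SE at n = 500", {
  set.seed(27)
  X <- cbind(1, rbinom(500, 1, 0.5))
  y <- exp(as.numeric(X %*% c(1, log(1.5))) + rnorm(500, sd = 1))
  f <- ols_log(y, X)
  expect_lt(abs(f$beta[2] - log(1.5)), 3 * f$se[2])
})

test_that("quasi-Poisson matches the two-group closed form", {
  X <- cbind(1, c(0, 0, 1, 1))
  f <- quasipoisson_glm(c(1, 3, 2, 6), X)
  expect_equal(unname(f$beta[2]), log(2), tolerance = 1e-8)
  expect_equal(f$dispersion_phi, 1.5, tolerance = 1e-8)
  # cross-check against the standard GLM fitter
  ref <- glm(c(1, 3, 2, 6) ~ c(0, 0, 1, 1), family = quasipoisson())
  expect_equal(unname(f$beta), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(f$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-5)

  expect_warning(f0 <- quasipoisson_glm(c(4, 4, 4, 4), X), "zero dispersion")
  expect_equal(unname(f0$beta[2]), 0, tolerance = 1e-10)
  expect_error(quasipoisson_glm(c(0, 0, 3, 5), X), "all-zero")
})

test_that("quasi-Poisson detects overdispersion in negative-binomial counts", {
  set.seed(28)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  y <- rnbinom(n, size = 2, mu = exp(1 + 0.5 * x))
  f <- quasipoisson_glm(y, cbind(1, x))
  expect_gt(f$dispersion_phi, 1)
  expect_lt(abs(f$beta[2] - 0.5), 3 * f$se[2])
})

test_that("percentage effect sizes follow the exp transform", {
  mkfit <- function(b, s) {
    structure(list(model = "ols_log", beta = c(`(Intercept)` = 0, x = b),
                   se = c(0.1, s), n_obs = 10L, residual_df = 8L,
                   lambda_hat = NA_real_, dispersion_phi = NA_real_),
              class = "range_fit")
  }
  e0 <- effect_size_percent(mkfit(0, 0))
  expect_equal(c(e0$percent, e0$ci_low, e0$ci_high), c(0, 0, 0))
  e1 <- effect_size_percent(mkfit(0.25, 0.1))
  expect_equal(e1$percent, 28.402542, tolerance = 1e-6)
  expect_equal(e1$ci_low, 5.548840, tolerance = 1e-5)
  expect_equal(e1$ci_high, 56.204584, tolerance = 1e-5)
  e2 <- effect_size_percent(mkfit(log(0.42), 0.01))
  expect_equal(e2$percent, -58, tolerance = 1e-10)
  expect_error(effect_size_percent(mkfit(0, 0), k = 9), "out of range")
})

test_that("tree aggregation computes mean and spread; rejects mixed designs", {
  tr <- simulate_tree(20, 1, seed = 29)
  X <- cbind(1, rep(c(0, 1), 10))
  y <- rnorm(20) + 5
  f1 <- gls_fit(y, X, diag(20)); f2 <- f1
  f1$beta[2] <- 0.2; f2$beta[2] <- 0.4
  ag <- aggregate_trees(list(f1, f2))
  expect_equal(ag$coef$mean[2], 0.3)
  expect_equal(ag$coef$spread[2], sd(c(0.2, 0.4)), tolerance = 1e-10)
  expect_equal(ag$coef$spread[2], 0.1414214, tolerance = 1e-6)

  same <- aggregate_trees(rep(list(f1), 100))
  expect_true(all(same$coef$spread == 0))

  colnames(X) <- c("a", "b")
  f3 <- gls_fit(y, X, diag(20))
  expect_error(aggregate_trees(list(f1, f3)), "designs")
})

test_that("PGLS fixed at lambda 0 reproduces log-OLS on ultrametric trees", {
  tr <- simulate_tree(50, 1, seed = 33)
  set.seed(34)
  y_raw <- exp(rnorm(50, 5, 1))
  X <- cbind(1, rbinom(50, 1, 0.5))
  C <- phylo_vcv(tr)
  f_gls <- gls_fit(log(y_raw), X, lambda_transform(C, 0))
  f_ols <- ols_log(y_raw, X)
  expect_equal(f_gls$beta, f_ols$beta, tolerance = 1e-8)
})

test_that("PGLS at lambda 1 is unbiased under pure Brownian motion", {
  nrep <- 60
  est <- numeric(nrep)
  for (r in 1:nrep) {
    tr <- simulate_tree(100, 1, seed = 700 + r)
    lab <- simulate_lifeform(tr, c(q01 = 1, q10 = 1), seed = 800 + r)
    y <- as.numeric(simulate_log_range(tr, lab, 5, 0.4, 1, 1,
                                       seed = 900 + r))
    X <- cbind(1, as.numeric(lab[tr$tip.label] == "epiphyte"))
    C <- phylo_vcv(tr)
    est[r] <- gls_fit(y, X, C)$beta[2]
  }
  mc_se <- sd(est) / sqrt(nrep)
  expect_lt(abs(mean(est) - 0.4), 3 * mc_se)
})

test_that("formula front-end and methods behave coherently", {
  tr <- simulate_tree(40, 1, seed = 37)
  lab <- simulate_lifeform(tr, seed = 38)
  y <- simulate_log_range(tr, lab, 7, 0.4, 0.8, 1, seed = 39)
  d <- data.frame(species = names(y), range_km2 = exp(as.numeric(y)),
                  lifeform = lab[names(y)], stringsAsFactors = FALSE)
  f <- fit_range_model(range_km2 ~ lifeform, d, model = "pgls", tree = tr)
  expect_s3_class(f, "range_fit")
  expect_named(coef(f), c("(Intercept)", "lifeformepiphyte"))
  expect_equal(dim(vcov(f)), c(2, 2))
  expect_equal(length(residuals(f)), nrow(d))
  expect_equal(predict(f, newdata = d[1:3, ]), predict(f)[1:3],
               tolerance = 1e-12)
  s <- summary(f)
  expect_s3_class(s, "summary.range_fit")
  expect_output(print(f), "pgls")
  sim <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(40L, 3L))
  # plot methods run without error on a null device
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(f))
})
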