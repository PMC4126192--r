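test_that("lasso path matches soft thresholding on an orthonormal design", {
  set.seed(8)
  X <- qr.Q(qr(matrix(rnorm(40 * 5), 40, 5)))
  theta <- c(2, -1.2, 0, 0.6, 0)
  y <- as.numeric(X %*% theta + rnorm(40, 0, 0.2))
  lam <- c(3, 1.5, 0.6, 0.1, 0.01)
  fit <- lasso_path(X, y, lambda = lam, tol = 1e-10)
  # objective sum(y - X t)^2 + lambda sum|t| with X'X = I:
  # t_j = sign(b_j) max(|b_j| - lambda/2, 0), b = X'y
  b <- as.numeric(crossprod(X, y))
  for (l in seq_along(lam)) {
    expected <- sign(b) * pmax(abs(b) - lam[l] / 2, 0)
    expect_equal(unname(fit$coef[, l]), expected, tolerance = 1e-8)
  }
})

test_that("the path hits OLS at negligible penalty and zero at lambda_max", {
  fx <- sparse_fixture(seed = 3)
  lam <- lambda_grid(fx$X, fx$y)
  fit <- lasso_path(fx$X, fx$y, lambda = c(lam[1], 1e-8), tol = 1e-10)
  expect_true(all(fit$coef[, 1] == 0))
  ols <- stats::lm.fit(fx$X, fx$y)$coefficients
  expect_equal(unname(fit$coef[, 2]), unname(ols), tolerance = 1e-5)
})

test_that("wlasso with unit weights reproduces the ordinary lasso path", {
  fx <- sparse_fixture(seed = 11)
  W1 <- matrix(1, nrow(fx$X), ncol(fx$X))
  wfit <- wlasso_path(fx$X, fx$y, W1, cd_tol = 1e-9)
  lfit <- lasso_path(fx$X, fx$y, lambda = wfit$lambda, tol = 1e-9)
  expect_lt(max(abs(wfit$coef - lfit$coef)), 1e-6)
  expect_true(all(wfit$converged))
  expect_lt(max(abs(wfit$obs_weights - 1)), 1e-12)
})

test_that("a row with zero weights on every active column is inert", {
  fx <- sparse_fixture(seed = 19)
  W <- matrix(1, nrow(fx$X), ncol(fx$X))
  W[1, ] <- 0                     # row 1 fully uncertain
  fx$y[1] <- 50                   # gross outlier that must not leak in
  lam <- lambda_grid(fx$X, fx$y)[20:60]
  full <- wlasso_path(fx$X, fx$y, W, lambda = lam, cd_tol = 1e-10)
  drop <- wlasso_path(fx$X[-1, ], fx$y[-1], W[-1, ], lambda = lam,
                      cd_tol = 1e-10)
  active <- full$df > 0 & drop$df > 0 & full$converged & drop$converged
  expect_true(any(active))
  expect_lt(max(abs(full$coef[, active] - drop$coef[, active])), 1e-6)
  # and the eliminated row's final weight is zero wherever the fit is active
  expect_true(all(full$obs_weights[1, active] == 0))
})

test_that("observation weights stay in [0,1] and iterations are bounded", {
  for (s in 1:20) {
    fx <- sparse_fixture(n = 40, p = 8, seed = 400 + s, frac_imputed = 0.15)
    fit <- suppressWarnings(wlasso_path(fx$X, fx$y, fx$W, tol = 1e-8,
                                        max_iter = 50))
    expect_true(all(fit$obs_weights >= 0 & fit$obs_weights <= 1))
    expect_true(all(fit$n_iter <= 50))
    expect_gt(mean(fit$converged), 0.8)
  }
})

test_that("weight traces start at the unit-weight initialization", {
  fx <- sparse_fixture(seed = 23)
  fit <- wlasso_path(fx$X, fx$y, fx$W, keep_trace = TRUE)
  tr <- fit$obs_weights_trace[[40]]
  expect_true(all(tr[1, ] == 1))
  expect_true(all(tr >= 0 & tr <= 1))
  # the reported weight vector is one of the visited iterates
  hit <- apply(tr, 1, function(r) max(abs(r - fit$obs_weights[, 40])))
  expect_lt(min(hit), 1e-12)
})

test_that("BIC selection matches the direct formula and prefers sparsity on ties", {
  fx <- sparse_fixture(seed = 31)
  lam <- lambda_grid(fx$X, fx$y)[seq(1, 100, by = 20)]
  fit <- lasso_path(fx$X, fx$y, lambda = lam)
  n <- length(fx$y)
  s2 <- sum(stats::lm.fit(cbind(1, fx$X), fx$y)$residuals^2) /
    (n - ncol(fx$X) - 1)
  sel <- bic_select(fit, fx$X, fx$y, s2 = s2)
  # brute-force evaluation, term by term
  bic_direct <- vapply(seq_along(lam), function(l) {
    rss <- sum((fx$y - fx$X %*% fit$coef[, l])^2)
    rss / s2 + sum(fit$coef[, l] != 0) * log(n)
  }, numeric(1))
  expect_equal(unname(sel$bic), bic_direct, tolerance = 1e-9)
  expect_equal(sel$index, which.min(bic_direct))
  # identical RSS, df 3 vs 5: the sparser model wins
  fake <- structure(list(lambda = c(2, 1),
                         coef = cbind(c(1, 1, 1, 0, 0), c(1, 1, 1, 0, 0)),
                         df = c(3, 5)), class = "lasso_path")
  Xf <- diag(5); yf <- c(1, 1, 1, 0, 0)
  pick <- bic_select(fake, Xf, yf, s2 = 1)
  expect_equal(pick$index, 1L)
  expect_equal(pick$lambda_star, 2)
  # a single-lambda grid returns that lambda
  one <- lasso_path(fx$X, fx$y, lambda = lam[3])
  expect_equal(bic_select(one, fx$X, fx$y)$lambda_star, lam[3])
})

test_that("adaptive lasso penalizes weak predictors harder", {
  set.seed(44)
  n <- 80
  X <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  colnames(X) <- c("strong", "weak")
  y <- as.numeric(X %*% c(1.5, 0.1) + rnorm(n, 0, 0.4))
  lam <- lambda_grid(X, y, nlambda = 60)
  ord <- lasso_path(X, y, lambda = lam)
  ada <- adaptive_lasso_path(X, y, gamma = 1, lambda = lam)
  first_in <- function(cf, j) which(cf[j, ] != 0)[1]
  # the strong predictor enters the adaptive path no later than the
  # ordinary one, the weak one no earlier
  expect_lte(first_in(ada$coef, 1), first_in(ord$coef, 1))
  expect_gte(first_in(ada$coef, 2), first_in(ord$coef, 2))
  # gamma = 0 gives unit penalty factors: identical to ordinary lasso
  a0 <- adaptive_lasso_path(X, y, gamma = 0, lambda = lam)
  expect_equal(a0$coef, ord$coef, tolerance = 1e-8)
  expect_error(adaptive_lasso_path(matrix(0, 3, 5), rnorm(3)), "p < n")
})

test_that("regression scan sweeps 67 thresholds and behaves at the extremes", {
  fx <- sparse_fixture(seed = 55)
  scan <- multiple_regression_scan(fx$X, fx$y)
  expect_equal(length(scan$thresholds), 67L)
  expect_equal(scan$thresholds[1:2], c(0.015, 0.030))
  expect_true(all(scan$selected[, ncol(scan$selected)] |
                    scan$p_values > max(scan$thresholds)))
  # threshold 1 selects everything, threshold 0 nothing
  s2 <- multiple_regression_scan(fx$X, fx$y, thresholds = c(0, 1))
  expect_equal(sum(s2$selected[, 1]), 0L)
  expect_equal(sum(s2$selected[, 2]), ncol(fx$X))
})

test_that("marker LRT scores match composed OLS fits and clip below 0.01", {
  set.seed(66)
  n <- 50
  X <- matrix(rbinom(n * 3, 1, 0.5), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(1, 0, -0.7) + rnorm(n, 0, 0.5))
  sc <- marker_lrt_scores(X, y)
  for (j in 1:3) {
    rss_full <- sum(residuals(lm(y ~ X))^2)
    rss_red <- sum(residuals(lm(y ~ X[, -j]))^2)
    raw <- (n / 2) * log10(rss_red / rss_full)
    expect_equal(sc$score[j], if (raw < 0.01) 0 else raw, tolerance = 1e-9)
  }
  expect_true(all(sc$score >= 0))
  # a duplicated column scores 0: dropping it leaves the fit unchanged
  Xd <- cbind(X, dup = X[, 1])
  scd <- marker_lrt_scores(Xd, y)
  expect_equal(scd$score[scd$marker == "dup"], 0)
  expect_equal(scd$score[scd$marker == "a"], 0)
})

test_that("all selection methods are permutation equivariant", {
  fx <- sparse_fixture(seed = 77)
  set.seed(78)
  perm <- sample(ncol(fx$X))
  lam <- lambda_grid(fx$X, fx$y)
  wf1 <- wlasso_path(fx$X, fx$y, fx$W, lambda = lam, cd_tol = 1e-10)
  wf2 <- wlasso_path(fx$X[, perm], fx$y, fx$W[, perm], lambda = lam,
                     cd_tol = 1e-10)
  ok <- wf1$converged & wf2$converged
  expect_lt(max(abs(wf1$coef[perm, ok] - wf2$coef[, ok])), 1e-5)
  lf1 <- lasso_path(fx$X, fx$y, lambda = lam, tol = 1e-10)
  lf2 <- lasso_path(fx$X[, perm], fx$y, lambda = lam, tol = 1e-10)
  expect_lt(max(abs(lf1$coef[perm, ] - lf2$coef[, ])), 1e-6)
  af1 <- adaptive_lasso_path(fx$X, fx$y, gamma = 1, lambda = lam,
                             tol = 1e-10)
  af2 <- adaptive_lasso_path(fx$X[, perm], fx$y, gamma = 1, lambda = lam,
                             tol = 1e-10)
  expect_lt(max(abs(af1$coef[perm, ] - af2$coef[, ])), 1e-6)
  ms1 <- multiple_regression_scan(fx$X, fx$y)
  ms2 <- multiple_regression_scan(fx$X[, perm], fx$y)
  expect_equal(unname(ms1$selected[perm, ]), unname(ms2$selected))
})

test_that("the lasso solver agrees with glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  fx <- sparse_fixture(n = 100, p = 15, seed = 91)
  fit <- lasso_path(fx$X, fx$y, tol = 1e-10)
  n <- length(fx$y)
  g <- glmnet::glmnet(fx$X, fx$y, lambda = fit$lambda / (2 * n),
                      standardize = FALSE, intercept = FALSE,
                      thresh = 1e-14)
  expect_lt(max(abs(as.matrix(g$beta) - fit$coef)), 1e-4)
})
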