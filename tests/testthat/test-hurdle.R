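test_that("OLS reproduces exact fits and the normal equations", {
  d <- tibble::tibble(y = c(1, 2, 3), x = c(1, 2, 3))
  f <- fit_ols(d, "y", "x")
  expect_equal(unname(coef(f$model)), c(0, 1), tolerance = 1e-12)
  expect_equal(sum(residuals(f$model)^2), 0, tolerance = 1e-20)

  d2 <- tibble::tibble(y = rep(2, 6), x = 1:6)
  f2 <- fit_ols(d2, "y", "x")
  expect_equal(f2$coefficients$estimate, 0)
  expect_equal(f2$coefficients$statistic, 0)

  set.seed(61)
  X <- cbind(x1 = rnorm(12), x2 = rnorm(12))
  y <- rnorm(12)
  d3 <- tibble::tibble(y = y, x1 = X[, 1], x2 = X[, 2])
  f3 <- fit_ols(d3, "y", c("x1", "x2"))
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)  # normal-equations oracle
  expect_equal(unname(coef(f3$model)), as.vector(beta), tolerance = 1e-10)

  # marginal (Type II) F equals the drop-one RSS comparison
  rss <- function(m) sum(residuals(m)^2)
  full <- lm(y ~ x1 + x2, data = d3)
  red <- lm(y ~ x2, data = d3)
  f_or <- (rss(red) - rss(full)) / (rss(full) / full$df.residual)
  expect_equal(f3$coefficients$statistic[1], f_or, tolerance = 1e-8)

  d4 <- d3; d4$x3 <- d4$x1 + d4$x2
  expect_error(fit_ols(d4, "y", c("x1", "x2", "x3")), "collinear")
  expect_error(fit_ols(d[1:2, ], "y", "x"), "n > p")
})

test_that("logistic fits match closed forms and a grid-search oracle", {
  d <- tibble::tibble(y = rep(c(0, 1), each = 10))
  f <- fit_binomial(d, "y", "1")
  expect_equal(unname(coef(f$model)), 0, tolerance = 1e-8)
  d2 <- tibble::tibble(y = rep(c(1, 0), c(15, 5)))
  f2 <- fit_binomial(d2, "y", "1")
  expect_equal(unname(coef(f2$model)), log(3), tolerance = 1e-8)

  # n = 8, one predictor: MLE against a two-stage dense grid search
  d3 <- tibble::tibble(x = c(-1.2, -0.8, -0.3, 0.1, 0.4, 0.9, 1.5, 2.0),
                       y = c(0, 1, 0, 0, 1, 1, 0, 1))
  f3 <- fit_binomial(d3, "y", "x")
  ll <- function(b0, b1) {
    eta <- b0 + b1 * d3$x
    sum(d3$y * eta - log1p(exp(eta)))
  }
  coarse <- expand.grid(b0 = seq(-6, 6, by = 0.05),
                        b1 = seq(-6, 6, by = 0.05))
  lls <- mapply(ll, coarse$b0, coarse$b1)
  best <- coarse[which.max(lls), ]
  fine <- expand.grid(b0 = seq(best$b0 - 0.06, best$b0 + 0.06, by = 5e-4),
                      b1 = seq(best$b1 - 0.06, best$b1 + 0.06, by = 5e-4))
  llf <- mapply(ll, fine$b0, fine$b1)
  bestf <- fine[which.max(llf), ]
  expect_equal(unname(coef(f3$model)), c(bestf$b0, bestf$b1),
               tolerance = 1e-3)

  expect_error(fit_binomial(tibble::tibble(y = rep(1, 10)), "y", "1"),
               "single-class")
  sep <- tibble::tibble(x = 1:10, y = rep(c(0, 1), each = 5))
  expect_error(fit_binomial(sep, "y", "x"), "separation|converge")
})

test_that("AICc follows its closed form and converges to AIC", {
  expect_equal(aicc(-5, 2, 10), 14 + 12 / 7)
  expect_lt(abs(aicc(-100, 3, 1e9) - (-2 * -100 + 2 * 3)), 1e-6)
  set.seed(62)
  for (i in 1:5) {
    llv <- runif(1, -50, -1); k <- sample(2:5, 1); n <- sample(10:40, 1)
    expect_equal(aicc(llv, k, n),
                 -2 * llv + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
  expect_error(aicc(-5, 9, 10), "n > k")
})

test_that("generalized R2 equals classical R2 for Gaussian fits", {
  set.seed(63)
  for (i in 1:5) {
    n <- sample(10:30, 1)
    d <- tibble::tibble(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n))
    f <- fit_ols(d, "y", c("x1", "x2"))
    m <- lm(y ~ x1 + x2, data = d)
    expect_equal(f$gen_r2, summary(m)$r.squared, tolerance = 1e-8)
    # monotone under nesting
    f1 <- fit_ols(d, "y", "x1")
    expect_gte(f$gen_r2, f1$gen_r2 - 1e-12)
  }
  m0 <- lm(rnorm(10) ~ 1)
  expect_equal(generalized_r2(m0, m0), 0)
  expect_error(generalized_r2(lm(rnorm(10) ~ 1), lm(rnorm(9) ~ 1)),
               "different n")
})

test_that("VIFs match brute-force auxiliary regressions", {
  X <- data.frame(x1 = c(1, -1, 1, -1, 1, -1, 1, -1),
                  x2 = c(1, 1, -1, -1, 1, 1, -1, -1))
  v <- vif_screen(X)
  expect_equal(unname(v$vif), c(1, 1), tolerance = 1e-12)
  expect_true(v$pass)

  set.seed(64)
  X4 <- as.data.frame(matrix(rnorm(80), 20, 4,
                             dimnames = list(NULL, paste0("x", 1:4))))
  X4$x2 <- X4$x1 * 0.9 + rnorm(20, sd = 0.1)
  v4 <- vif_screen(X4)
  brute <- vapply(1:4, function(j) {
    r2 <- summary(lm(X4[[j]] ~ ., data = X4[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(v4$vif), brute, tolerance = 1e-8)

  Xc <- data.frame(x1 = rnorm(10))
  Xc$x2 <- 2 * Xc$x1
  vc <- vif_screen(Xc)
  expect_true(all(is.infinite(vc$vif)))
  expect_false(vc$pass)
  expect_error(vif_screen(data.frame(x1 = rnorm(5), x2 = rep(1, 5))),
               "zero-variance")
})

test_that("standardized coefficients are scale-free and match a refit", {
  set.seed(65)
  d <- tibble::tibble(y = rnorm(15), x1 = rnorm(15, sd = 4),
                      x2 = rnorm(15, sd = 0.2))
  f <- fit_ols(d, "y", c("x1", "x2"))
  std <- standardize_coefficients(f)
  dz <- dplyr::mutate(d, x1 = as.numeric(scale(x1)),
                      x2 = as.numeric(scale(x2)))
  fz <- fit_ols(dz, "y", c("x1", "x2"))
  # refit oracle: coefficients on z-scored predictors
  sd_n <- function(x) sd(x)  # sample sd, as used in scale()
  expect_equal(unname(std),
               unname(coef(fz$model)[c("x1", "x2")]), tolerance = 1e-10)
  # pre-standardized X: standardized equals raw
  expect_equal(unname(standardize_coefficients(fz)),
               unname(coef(fz$model)[c("x1", "x2")]), tolerance = 1e-10)
  # multiplying a predictor by 10 leaves its standardized slope unchanged
  d10 <- dplyr::mutate(d, x1 = 10 * x1)
  f10 <- fit_ols(d10, "y", c("x1", "x2"))
  expect_equal(standardize_coefficients(f10)[["x1"]], std[["x1"]],
               tolerance = 1e-10)
})

test_that("the permutation test matches exhaustive enumeration", {
  y <- c(0.3, -1.2, 0.8, 2.1, -0.5)
  x <- 1:5
  slope <- function(yy) coef(lm.fit(cbind(1, x), yy))[2]
  perms <- all_permutations(5)
  b_obs <- slope(y)
  b_all <- apply(perms, 1, function(p) slope(y[p]))
  p_exhaustive <- mean(abs(b_all) >= abs(b_obs))
  pt <- permutation_test(y, x, n_perm = 10000, seed = 99)
  expect_lt(abs(pt$p_value - p_exhaustive), 0.02)
  # determinism and the p >= 1/(n+1) floor
  pt2 <- permutation_test(y, x, n_perm = 10000, seed = 99)
  expect_identical(pt$p_value, pt2$p_value)
  expect_gte(pt$p_value, 1 / 10001)
  expect_equal(permutation_test(rep(1, 6), 1:6, n_perm = 200)$p_value, 1)
  expect_error(permutation_test(y, x, n_perm = 0), "n_perm")
})

test_that("the two-step model excludes zeros exactly and degrades gracefully", {
  d <- tibble::tibble(P = c(0, 0, 3, 30, 300), x = c(0.2, 1.1, 0.5, 2, 3.5))
  h <- fit_two_step(d, "P", "x")
  expect_equal(h$zero_count, 2)
  expect_equal(h$step2$n_used, 3)
  # step 2 is exactly OLS of log10(P) on the positive subset
  or <- lm(log10(P) ~ x, data = d[d$P > 0, ])
  expect_equal(unname(coef(h$step2$model)), unname(coef(or)),
               tolerance = 1e-12)
  expect_equal(h$step2$loglik, as.numeric(logLik(or)), tolerance = 1e-10)

  # no zeros: step 1 unfit, step 2 is plain OLS on all n
  d2 <- tibble::tibble(P = c(2, 5, 9, 13, 40, 80), x = rnorm(6))
  h2 <- fit_two_step(d2, "P", "x")
  expect_null(h2$step1)
  expect_match(h2$unfit[["step1"]], "single-class")
  expect_equal(h2$step2$n_used, 6)

  # all zeros: both steps unfit
  h3 <- fit_two_step(tibble::tibble(P = rep(0, 6), x = rnorm(6)), "P", "x")
  expect_null(h3$step1)
  expect_null(h3$step2)

  # too few positives for the linear step
  h4 <- fit_two_step(tibble::tibble(P = c(0, 0, 0, 4, 7), x = rnorm(5)),
                     "P", "x")
  expect_null(h4$step2)
  expect_match(h4$unfit[["step2"]], "positive")
})
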