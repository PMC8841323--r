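#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 * loglik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters (including the residual
#'   variance for Gaussian models).
#' @param n number of observations.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) abort("AICc requires n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Likelihood-ratio based generalized R-squared
#'
#' `R2 = 1 - exp(-(2/n) * (loglik_full - loglik_null))`, with the null the
#' intercept-only model on the same data. For Gaussian linear models this
#' coincides with the classical R-squared.
#'
#' @param fit,null_fit fitted models (`lm`/`glm` objects or `fit_result`s)
#'   on identical data.
#' @return Value in `[0, 1)`.
#' @export
generalized_r2 <- function(fit, null_fit) {
  ll <- function(m) {
    if (inherits(m, "fit_result")) list(ll = m$loglik, n = m$n_used)
    else list(ll = as.numeric(logLik(m)), n = stats::nobs(m))
  }
  f <- ll(fit); n0 <- ll(null_fit)
  if (f$n != n0$n) abort("full and null fits use different n")
  1 - exp(-(2 / f$n) * (f$ll - n0$ll))
}

#' Standardized coefficients
#'
#' Re-expresses slope coefficients for z-scored predictors
#' (`beta_std = beta * sd(x)`); the response stays on its model scale, so
#' standardized coefficients are comparable across predictors without
#' changing the printed response units.
#'
#' @param fit a `fit_result`.
#' @return Named vector of standardized slopes (intercept excluded).
#' @export
standardize_coefficients <- function(fit) {
  mm <- model.matrix(fit$model)
  terms <- setdiff(colnames(mm), "(Intercept)")
  sds <- apply(mm[, terms, drop = FALSE], 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance predictor: %s",
                  paste(terms[sds == 0], collapse = ", ")))
  }
  coef(fit$model)[terms] * sds
}

new_fit_result <- function(step, model, null_model, stat_table, stat_type) {
  n <- stats::nobs(model)
  ll <- as.numeric(logLik(model))
  k <- attr(logLik(model), "df")
  terms <- setdiff(colnames(model.matrix(model)), "(Intercept)")
  res <- structure(
    list(step = step,
         n_used = n,
         df_residual = stats::df.residual(model),
         k = k,
         loglik = ll,
         aicc = if (n > k + 1) aicc(ll, k, n) else NA_real_,
         gen_r2 = NA_real_,
         coefficients = stat_table,
         model = model),
    class = "fit_result")
  res$gen_r2 <- generalized_r2(model, null_model)
  std <- tryCatch(standardize_coefficients(res), error = function(e) {
    setNames(rep(NA_real_, length(terms)), terms)
  })
  res$coefficients$std_estimate <- unname(std[res$coefficients$term])
  res$coefficients$stat_type <- rep(stat_type, nrow(res$coefficients))
  res$coefficients <- res$coefficients[
    , c("term", "estimate", "std_estimate", "statistic", "stat_type",
        "p_value")]
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, residual df = %d, AICc = %.2f, gen. R2 = %.3f\n",
              x$step, x$n_used, x$df_residual, x$aicc, x$gen_r2))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

check_design <- function(data, response, predictors) {
  cols <- c(response, predictors)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (anyNA(data[, cols])) abort("missing values in model data")
  mm <- model.matrix(reformulate(predictors), data)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    abort(sprintf("rank-deficient design; collinear column(s): %s",
                  paste(aliased, collapse = ", ")))
  }
  invisible(mm)
}

#' Ordinary least squares with marginal F tests
#'
#' Fits a Gaussian linear model and reports, per predictor, the marginal
#' (Type II) F statistic and p-value, the Gaussian log-likelihood, AICc
#' (parameter count includes the residual variance), the
#' likelihood-ratio generalized R-squared against the intercept-only model,
#' and standardized coefficients.
#'
#' @param data data frame.
#' @param response name of the response column.
#' @param predictors character vector of predictor columns.
#' @param step label stored in the result (`"single_linear"` by default;
#'   the hurdle wrapper sets `"linear"`).
#' @return A `fit_result`.
#' @export
fit_ols <- function(data, response, predictors, step = "single_linear") {
  check_design(data, response, predictors)
  n <- nrow(data)
  if (n <= length(predictors) + 1) abort("need n > p + 1 observations")
  m <- lm(reformulate(predictors, response), data = data)
  null <- lm(reformulate("1", response), data = data)
  an <- tryCatch(car::Anova(m, type = 2), error = function(e) NULL)
  if (!is.null(an)) {
    idx <- match(predictors, rownames(an))
    fval <- an[["F value"]][idx]
    pval <- an[["Pr(>F)"]][idx]
    ss <- an[["Sum Sq"]][idx]
    rss <- an["Residuals", "Sum Sq"]
  } else {
    # car refuses degenerate fits (zero residual variance); fall back to
    # the defining drop-one sums of squares
    rss <- sum(residuals(m)^2)
    ss <- vapply(predictors, function(pr) {
      kept <- setdiff(predictors, pr)
      red <- lm(reformulate(if (length(kept)) kept else "1", response),
                data = data)
      sum(residuals(red)^2) - rss
    }, numeric(1))
    fval <- (ss / 1) / (rss / m$df.residual)
    pval <- stats::pf(fval, 1, m$df.residual, lower.tail = FALSE)
  }
  # degenerate sums of squares: a constant response has F = 0 by
  # convention; a perfect fit sends F to infinity
  fval <- unname(fval); pval <- unname(pval); ss <- unname(ss)
  tss <- sum((data[[response]] - mean(data[[response]]))^2)
  fval[ss <= 1e-300] <- 0
  pval[ss <= 1e-300] <- 1
  fval[ss > 1e-300 & rss <= 1e-300] <- Inf
  pval[ss > 1e-300 & rss <= 1e-300] <- 0
  if (tss <= 1e-300) {
    fval <- rep(0, length(fval))
    pval <- rep(1, length(pval))
  }
  stat_table <- tibble(
    term = predictors,
    estimate = unname(coef(m)[predictors]),
    statistic = fval,
    p_value = pval)
  new_fit_result(step, m, null, stat_table, "F")
}

#' Logistic regression with likelihood-ratio tests
#'
#' Fits a binomial GLM for a presence/absence response and reports per
#' predictor the Type II likelihood-ratio chi-squared statistic and
#' p-value, plus log-likelihood, AICc and generalized R-squared.
#'
#' @param data data frame.
#' @param response name of the 0/1 (or logical) response column.
#' @param predictors character vector of predictor columns; `"1"` fits an
#'   intercept-only model.
#' @return A `fit_result` with `step = "binomial"`.
#' @export
fit_binomial <- function(data, response, predictors) {
  y <- as.integer(as.logical(data[[response]]))
  if (length(unique(y)) < 2) {
    abort("single-class response: both presences and absences are required")
  }
  intercept_only <- identical(predictors, "1")
  if (!intercept_only) check_design(data, response, predictors)
  dat <- data
  dat[[response]] <- y
  m <- suppressWarnings(
    glm(reformulate(predictors, response), family = stats::binomial(),
        data = dat))
  if (!m$converged) abort("logistic fit did not converge")
  if (!intercept_only && m$deviance < 1e-6) {
    abort("perfect separation: presence is fully determined by the predictors")
  }
  null <- glm(reformulate("1", response), family = stats::binomial(),
              data = dat)
  if (intercept_only) {
    stat_table <- tibble(term = character(), estimate = double(),
                         statistic = double(), p_value = double())
  } else {
    an <- suppressWarnings(car::Anova(m, type = 2, test.statistic = "LR"))
    idx <- match(predictors, rownames(an))
    stat_table <- tibble(
      term = predictors,
      estimate = unname(coef(m)[predictors]),
      statistic = an[["LR Chisq"]][idx],
      p_value = an[["Pr(>Chisq)"]][idx])
  }
  new_fit_result("binomial", m, null, stat_table, "LR_chisq")
}

#' Two-step (hurdle) model for zero-inflated predator counts
#'
#' Step one fits a binomial model on the presence/absence of the count
#' response; step two fits a Gaussian linear model on the log10-transformed
#' counts, excluding the zero-count landscapes. The two steps are
#' estimated independently. A step is marked unfit (with the reason
#' recorded) when its data are degenerate: no zeros or no positives for
#' step one, fewer than `p + 2` positive counts for step two.
#'
#' @param data data frame containing the count response and predictors.
#' @param response name of the non-negative count column.
#' @param predictors character vector of predictor columns.
#' @return A `hurdle_result`: `step1`, `step2` (`fit_result` or `NULL`),
#'   `unfit` (named reasons), `zero_count`, `n`.
#' @export
fit_two_step <- function(data, response, predictors) {
  y <- data[[response]]
  if (is.null(y)) abort(sprintf("no column `%s`", response))
  if (any(y < 0)) abort("count response must be >= 0")
  n <- length(y)
  zero_count <- sum(y == 0)
  unfit <- character()

  step1 <- NULL
  if (zero_count == 0 || zero_count == n) {
    unfit["step1"] <- "single-class presence response"
  } else {
    d1 <- data
    d1$.presence <- as.integer(y > 0)
    step1 <- tryCatch(fit_binomial(d1, ".presence", predictors),
                      error = function(e) {
                        unfit["step1"] <<- conditionMessage(e)
                        NULL
                      })
  }

  step2 <- NULL
  n_pos <- n - zero_count
  if (n_pos < length(predictors) + 2) {
    unfit["step2"] <- sprintf(
      "only %d positive count(s) for %d predictor(s)", n_pos,
      length(predictors))
  } else {
    d2 <- data[y > 0, , drop = FALSE]
    d2$.log10_count <- log10(y[y > 0])
    step2 <- fit_ols(d2, ".log10_count", predictors, step = "linear")
  }

  structure(
    list(step1 = step1, step2 = step2, unfit = unfit,
         zero_count = zero_count, n = n, response = response,
         predictors = predictors),
    class = "hurdle_result")
}

#' @export
print.hurdle_result <- function(x, ...) {
  cat(sprintf("Two-step model of `%s` (%d zeros of %d)\n", x$response,
              x$zero_count, x$n))
  if (!is.null(x$step1)) print(x$step1) else
    cat(sprintf("  step 1 unfit: %s\n", x$unfit[["step1"]]))
  if (!is.null(x$step2)) print(x$step2) else
    cat(sprintf("  step 2 unfit: %s\n", x$unfit[["step2"]]))
  invisible(x)
}

#' Variance inflation factors with a screening verdict
#'
#' VIFs are computed with `car::vif()`; perfect collinearity is reported
#' as infinite VIF rather than an error. The screening passes when every
#' VIF stays below the threshold (3 by default).
#'
#' @param X data frame or matrix of predictors (at least two columns).
#' @param threshold screening threshold.
#' @return List with `vif` (named vector) and `pass` (logical).
#' @export
vif_screen <- function(X, threshold = 3) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) abort("VIF screening needs at least two predictors")
  vars <- vapply(X, var, numeric(1))
  if (any(vars == 0)) {
    abort(sprintf("zero-variance predictor: %s",
                  paste(names(X)[vars == 0], collapse = ", ")))
  }
  mm <- cbind(1, as.matrix(X))
  if (qr(mm)$rank < ncol(mm)) {
    v <- setNames(rep(Inf, ncol(X)), names(X))
    # columns not involved in the dependency still get finite VIFs
    for (j in seq_len(ncol(X))) {
      others <- as.matrix(X[, -j, drop = FALSE])
      r2 <- suppressWarnings(summary(lm(X[[j]] ~ others))$r.squared)
      v[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }
    return(list(vif = v, pass = FALSE))
  }
  d <- X
  d$.y <- seq_len(nrow(X))
  v <- car::vif(lm(.y ~ ., data = d))
  list(vif = v, pass = all(v < threshold))
}

#' Permutation test for a regression coefficient
#'
#' Refits the linear model on permuted responses and reports the
#' two-sided permutation p-value of the target coefficient,
#' `p = (1 + #{|b_perm| >= |b_obs|}) / (n_perm + 1)` (the observed data
#' count as one permutation, so p >= 1/(n_perm + 1)).
#'
#' @param y response vector.
#' @param x predictor vector or matrix.
#' @param term column of `x` whose coefficient is tested (default first).
#' @param n_perm number of permutations (500 by default).
#' @param seed integer seed for the permutation stream.
#' @return A `permutation_result`: `observed`, `p_value`, `n_perm`,
#'   `seed`.
#' @export
permutation_test <- function(y, x, term = 1L, n_perm = 500L, seed = 1L) {
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  x <- as.matrix(x)
  if (nrow(x) != length(y)) abort("`y` and `x` sizes differ")
  mm <- cbind(`(Intercept)` = 1, x)
  stat <- function(yy) lm.fit(mm, yy)$coefficients[[term + 1L]]
  obs <- stat(y)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(y)), numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  structure(list(observed = obs, p_value = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test: observed = %.4g, p = %.4f (%d permutations, seed %d)\n",
              x$observed, x$p_value, x$n_perm, x$seed))
  invisible(x)
}
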