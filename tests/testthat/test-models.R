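test_that("standardization produces shared zero-mean unit-sd designs", {
  run <- small_run()
  d <- standardize(run$labels)
  expect_true(all(abs(colMeans(d$ind$X)) < 1e-10))
  expect_equal(unname(apply(d$ind$X, 2, sd)), rep(1, 5), tolerance = 1e-10)
  expect_identical(d$ind$X, d$pop$X)
  expect_identical(d$ind$y, run$labels$core_ind)
  expect_identical(d$pop$y, run$labels$core_pop)
  expect_s3_class(d$pop$group, "factor")
  expect_null(d$ind$group)

  # idempotence: standardizing already-standardized covariates is a no-op
  lab2 <- run$labels
  lab2[HABITAT_COVARIATES] <- as.data.frame(d$ind$X)
  d2 <- standardize(lab2)
  expect_lt(max(abs(d2$ind$X - d$ind$X)), 1e-10)

  lab3 <- run$labels
  lab3$rock <- 50
  expect_error(standardize(lab3), "rock")
  expect_error(standardize(run$labels[1:10, ]), "50")
})

test_that("VIF matches a direct OLS oracle and flags collinearity", {
  set.seed(31)
  # centered, mutually orthogonal columns
  Xo <- qr.Q(qr(cbind(1, matrix(rnorm(200 * 5), 200, 5))))[, 2:6]
  colnames(Xo) <- HABITAT_COVARIATES
  expect_equal(vif(Xo)$vif, rep(1, 5), tolerance = 1e-8)

  # known equicorrelated structure: compare to lm()-based oracle
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  X3 <- matrix(rnorm(500 * 3), 500, 3) %*% chol(S)
  colnames(X3) <- c("a", "b", "c")
  got <- vif(X3)$vif
  oracle <- vapply(1:3, function(j) {
    r2 <- summary(lm(X3[, j] ~ X3[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-8)

  # duplicated column: infinite VIF, flagged, with a warning (not an error)
  Xd <- cbind(Xo[, 1:4], dup = Xo[, 1])
  expect_warning(res <- vif(Xd), "collinear")
  expect_true(is.infinite(res$vif[5]))
  expect_true(res$flagged[5])
})

test_that("logistic fits match closed forms and recover planted effects", {
  d <- make_design(400, rep(0, 5), seed = 51, intercept = 0.7)
  null_fit <- fit_logistic(d, character(0))
  expect_equal(unname(null_fit$coef[1]), qlogis(mean(d$y)), tolerance = 1e-8)
  expect_equal(null_fit$aic, 2 * null_fit$k - 2 * null_fit$logLik)

  beta <- c(0.5, -0.5, 0, 0, 0)
  d2 <- make_design(5000, beta, seed = 52)
  fit <- fit_logistic(d2)
  expect_true(all(abs(fit$coef[-1] - beta) < 3 * fit$se[-1]))
  expect_equal(fit$aic, 2 * 6 - 2 * fit$logLik)

  # agreement with the reference IRLS implementation
  ref <- glm(d2$y ~ d2$X, family = binomial())
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)

  # separation errors
  dsep <- d2
  dsep$y <- as.integer(dsep$X[, 1] > 0)
  expect_error(fit_logistic(dsep), "separation|converge")
  dconst <- d2; dconst$y <- rep(1L, 5000)
  expect_error(fit_logistic(dconst), "both classes")
})

test_that("mixed logistic collapses to the pooled fit without group effects", {
  d <- make_design(600, c(1, -1, 0, 0, 0), seed = 53, sigma_u = 0,
                   n_groups = 20)
  mix <- fit_mixed_logistic(d)
  if (mix$boundary) {
    plain <- fit_logistic(d)
    expect_lt(max(abs(mix$coef - plain$coef)), 1e-3)
  }
  expect_lt(mix$re_variance, 0.05)
  expect_equal(mix$aic, 2 * mix$k - 2 * mix$logLik)
  expect_equal(mix$k, 7)  # intercept + 5 slopes + variance
})

test_that("adaptive quadrature agrees with a denser node grid", {
  d <- make_design(450, c(1, -1, 0, 0, 0), seed = 54, sigma_u = 1,
                   n_groups = 15)
  f9 <- fit_mixed_logistic(d, nAGQ = 9)
  f25 <- fit_mixed_logistic(d, nAGQ = 25)
  expect_lt(abs(f9$logLik - f25$logLik), 1e-4)
})

test_that("full model averaging reproduces the weight formulas exactly", {
  # two tied models, coefficient present in only one: average is b / 2
  mk_fit <- function(terms, coef, se, logLik, k)
    structure(list(terms = terms, coef = coef, se = se, logLik = logLik,
                   aic = 2 * k - 2 * logLik, k = k), class = "fitted_model")
  b <- 0.8
  f1 <- mk_fit("canopy", c("(Intercept)" = 0.1, canopy = b),
               c("(Intercept)" = 0.05, canopy = 0.1), logLik = -100, k = 2)
  f2 <- mk_fit(character(0), c("(Intercept)" = 0.1),
               c("(Intercept)" = 0.05), logLik = -98, k = 0)  # ties the AIC
  f2$aic <- f1$aic
  avg <- udlevels:::average_fits(list(f1, f2), HABITAT_COVARIATES, cut = 2)
  expect_equal(avg$coefficients$estimate[avg$coefficients$term == "canopy"],
               b / 2)
  expect_equal(sum(avg$ledger$weight), 1)
  # unconditional SE by hand: w = 1/2 each, absent model contributes SE 0
  se_hand <- 0.5 * sqrt(0.1^2 + (b - b / 2)^2) + 0.5 * sqrt(0 + (0 - b / 2)^2)
  expect_equal(avg$coefficients$se[avg$coefficients$term == "canopy"],
               se_hand)

  # one dominant covariate: the averaging set is the full candidate and the
  # averaged coefficient equals its fit
  d <- make_design(800, c(2, 0, 0, 0, 0), seed = 55)
  one <- structure(list(y = d$y, X = d$X[, 1, drop = FALSE], group = NULL,
                        names = "canopy"), class = "design_matrix")
  avg1 <- all_subsets_average(one, cfg = run_config())
  if (sum(avg1$ledger$in_set) == 1) {
    fit1 <- fit_logistic(one)
    expect_equal(
      avg1$coefficients$estimate[avg1$coefficients$term == "canopy"],
      unname(fit1$coef["canopy"]))
  }

  # oracle reimplementation of the averaging formulas on all 32 real fits
  d5 <- make_design(500, c(0.4, -0.3, 0.2, 0, 0), seed = 56)
  avg5 <- all_subsets_average(d5, cfg = run_config())
  expect_equal(nrow(avg5$ledger), 32)
  subsets <- unlist(lapply(0:5, function(k)
    combn(HABITAT_COVARIATES, k, simplify = FALSE)), recursive = FALSE)
  fits <- lapply(subsets, function(s) fit_logistic(d5, s))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  delta <- aic - min(aic)
  keep <- delta < 2
  w <- exp(-delta[keep] / 2); w <- w / sum(w)
  for (v in HABITAT_COVARIATES) {
    bvec <- vapply(fits[keep], function(f)
      if (v %in% names(f$coef)) unname(f$coef[v]) else 0, numeric(1))
    svec <- vapply(fits[keep], function(f)
      if (v %in% names(f$se)) unname(f$se[v]) else 0, numeric(1))
    bbar <- sum(w * bvec)
    sbar <- sum(w * sqrt(svec^2 + (bvec - bbar)^2))
    expect_equal(avg5$coefficients$estimate[avg5$coefficients$term == v],
                 bbar, tolerance = 1e-10)
    expect_equal(avg5$coefficients$se[avg5$coefficients$term == v],
                 sbar, tolerance = 1e-10)
  }
})

test_that("the Wald level contrast matches the chi-square oracle", {
  mk_avg <- function(est, se) {
    ct <- data.frame(term = c("(Intercept)", HABITAT_COVARIATES),
                     estimate = c(0, est), se = c(0.1, se))
    ct$ci_lo <- ct$estimate - 1.96 * ct$se
    ct$ci_hi <- ct$estimate + 1.96 * ct$se
    structure(list(coefficients = ct, ledger = NULL,
                   covariates = HABITAT_COVARIATES),
              class = "averaged_model")
  }
  a <- mk_avg(c(3, 1, 0, 0, 0), rep(1, 5))
  b <- mk_avg(c(0, 1, 0, 0, 0), rep(1, 5))
  ct <- wald_level_test(a, b)
  expect_equal(ct$W[1], 3^2 / (1 + 1))
  expect_equal(ct$p[1], pchisq(4.5, 1, lower.tail = FALSE))
  expect_equal(ct$p[1], 0.0339, tolerance = 1e-3)
  # identical coefficients: W = 0, p = 1
  expect_equal(ct$W[2], 0)
  expect_equal(ct$p[2], 1)

  zero <- mk_avg(c(1, 0, 0, 0, 0), c(0, 1, 1, 1, 1))
  expect_error(wald_level_test(a, zero), "zero")
})

test_that("marginal effect curves follow the averaged linear predictor", {
  ct <- data.frame(term = c("(Intercept)", HABITAT_COVARIATES),
                   estimate = c(0.5, 0.8, 0, 0, 0, 0),
                   se = c(0.2, 0.3, 0.1, 0.1, 0.1, 0.1))
  ct$ci_lo <- ct$estimate - 1.96 * ct$se
  ct$ci_hi <- ct$estimate + 1.96 * ct$se
  avg <- structure(list(coefficients = ct, ledger = NULL,
                        covariates = HABITAT_COVARIATES),
                   class = "averaged_model")
  # zero-slope covariate: flat curve at plogis(intercept)
  flat <- marginal_effects(avg, "cwd")
  expect_equal(unique(round(flat$prob, 12)), plogis(0.5))
  # positive slope: strictly increasing
  up <- marginal_effects(avg, "canopy")
  expect_true(all(diff(up$prob) > 0))
  # delta-method CI at grid = 0 (oracle recomputation through the link)
  at0 <- up[abs(up$value) < 1e-9, ]
  expect_equal(at0$ci_lo, plogis(0.5 - 1.96 * 0.2))
  expect_equal(at0$ci_hi, plogis(0.5 + 1.96 * 0.2))
  expect_warning(marginal_effects(avg, "canopy", grid = seq(-4, 4, 1)),
                 "3 standardized")
  expect_error(marginal_effects(avg, "elevation"), "not in model")
})
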