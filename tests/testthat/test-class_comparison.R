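# table of core rows with controllable class-specific covariate shifts
make_label_table <- function(n_per_class, shifts = NULL, seed = 1,
                             classes = REPRO_CLASSES) {
  with_seed(seed, {
    rows <- lapply(seq_along(classes), function(i) {
      n <- n_per_class
      df <- data.frame(obs_id = seq_len(n) + i * 10000,
                       animal_id = sprintf("A%d", i), season_id = "s1",
                       class = classes[i], stringsAsFactors = FALSE)
      for (v in HABITAT_COVARIATES) {
        mu <- 50 + if (!is.null(shifts)) shifts[classes[i], v] else 0
        df[[v]] <- pmin(pmax(rnorm(n, mu, 12), 0), 100)
      }
      df$core_ind <- 1L
      df$core_pop <- rbinom(n, 1, 0.4)
      df
    })
    do.call(rbind, rows)
  })
}

test_that("a two-group multinomial model equals the binary logit", {
  tab <- make_label_table(120, classes = c("gravid_female", "male"))
  fit <- fit_multinomial(tab, "class")
  expect_equal(fit$reference, "gravid_female")
  Z <- scale(as.matrix(tab[HABITAT_COVARIATES]))
  ref <- glm(I(tab$class == "male") ~ Z, family = binomial())
  expect_lt(max(abs(fit$coef["male", ] - coef(ref))), 1e-6)
  # fitted class probabilities sum to one
  expect_equal(unname(rowSums(fit$fitted)), rep(1, nrow(tab)),
               tolerance = 1e-10)

  # the 2-group EMM difference equals the binary-logit intercept at the
  # covariate means (which are zero under standardization)
  emm <- emm_pairwise(fit)
  d <- emm$contrasts$difference[1]
  expect_lt(abs(abs(d) - abs(unname(coef(ref)[1]))), 1e-6)
})

test_that("EMM contrasts agree with the emmeans package on latent means", {
  skip_if_not_installed("emmeans")
  shifts <- matrix(0, 3, 5, dimnames = list(REPRO_CLASSES,
                                            HABITAT_COVARIATES))
  shifts["male", "ground_veg"] <- 12
  shifts["gravid_female", "cwd"] <- 15
  tab <- make_label_table(100, shifts, seed = 3)
  fit <- fit_multinomial(tab, "class")
  nn <- nnet::multinom(
    group ~ canopy + cwd + ground_veg + rock + woody_veg,
    data = fit$rows, trace = FALSE, maxit = 1000, reltol = 1e-14)
  em <- emmeans::emmeans(nn, pairwise ~ group, mode = "latent")
  em_ct <- as.data.frame(em$contrasts)
  ours <- emm_pairwise(fit)$contrasts
  # emmeans orders levels as fitted (reference first)
  for (i in seq_len(nrow(em_ct))) {
    pair <- strsplit(as.character(em_ct$contrast[i]), " - ")[[1]]
    pair <- gsub("[()]", "", pair)
    j <- match(TRUE, vapply(seq_len(nrow(ours)), function(k)
      setequal(strsplit(ours$contrast[k], " - ")[[1]], pair), logical(1)))
    flip <- if (startsWith(ours$contrast[j], pair[1])) 1 else -1
    expect_equal(flip * ours$difference[j], em_ct$estimate[i],
                 tolerance = 1e-6)
    expect_equal(ours$se[j], em_ct$SE[i], tolerance = 1e-6)
  }
})

test_that("null covariates give no class separation; planted shifts do", {
  tab0 <- make_label_table(100, seed = 11)
  fit0 <- fit_multinomial(tab0, "class")
  expect_true(all(abs(fit0$coef[, -1] / fit0$se[, -1]) < 3))
  emm0 <- emm_pairwise(fit0)
  expect_false(any(emm0$contrasts$significant))
  # antisymmetry through the latent means: d(A,B) = eta_A - eta_B
  eta <- emm0$emmeans$latent_mean
  names(eta) <- emm0$emmeans$group
  for (i in seq_len(nrow(emm0$contrasts))) {
    pr <- strsplit(emm0$contrasts$contrast[i], " - ")[[1]]
    expect_equal(emm0$contrasts$difference[i],
                 unname(eta[pr[1]] - eta[pr[2]]), tolerance = 1e-10)
  }

  shifts <- matrix(0, 3, 5, dimnames = list(REPRO_CLASSES,
                                            HABITAT_COVARIATES))
  shifts["gravid_female", "cwd"] <- 15
  shifts["male", "ground_veg"] <- 12
  tab1 <- make_label_table(120, shifts, seed = 12)
  fit1 <- fit_multinomial(tab1, "class")
  expect_lt(fit1$coef["male", "cwd"], 0)
  expect_lt(fit1$coef["nongravid_female", "cwd"], 0)
  expect_gt(fit1$coef["male", "ground_veg"], 0)
  # model logLik beats the intercept-only multinomial
  p0 <- table(tab1$class) / nrow(tab1)
  ll0 <- sum(log(p0[tab1$class]))
  expect_gt(fit1$logLik, ll0)

  small <- tab1[c(1:245), ]  # third class reduced to 5 rows
  expect_error(fit_multinomial(small, "class"), "fewer than 10")
})

test_that("the level model contrasts individual against population cores", {
  run <- small_run()
  fit <- fit_multinomial(run$labels, "level")
  expect_equal(fit$reference, "individual")
  expect_setequal(fit$groups, c("individual", "population"))
  # rows: one per core membership, so both-core points appear twice
  n_expected <- sum(run$labels$core_ind) + sum(run$labels$core_pop)
  expect_equal(fit$n, n_expected)
  # planted structure: population cores sit in high-canopy, high-rock
  # hibernaculum habitat relative to individual summer cores
  expect_gt(fit$coef["population", "canopy"] +
              fit$coef["population", "rock"], 0)
})

test_that("Bartlett's sphericity statistic matches the closed formula", {
  # df for five covariates
  set.seed(41)
  X <- matrix(rnorm(300 * 5), 300, 5)
  got <- bartlett_sphericity(X)
  expect_equal(got$df, 10)
  # direct formula oracle
  R <- cor(X)
  chi_oracle <- -(300 - 1 - (2 * 5 + 5) / 6) * log(det(R))
  expect_equal(got$chisq, chi_oracle, tolerance = 1e-6)

  # exactly uncorrelated columns: statistic collapses, p near 1
  Xo <- qr.Q(qr(cbind(1, X)))[, 2:6]  # centered and mutually orthogonal
  goto <- bartlett_sphericity(Xo)
  expect_lt(goto$chisq, 1e-6)
  expect_gt(goto$p, 0.999)

  # equicorrelated columns are decisively non-spherical
  S <- matrix(0.5, 5, 5); diag(S) <- 1
  Xe <- matrix(rnorm(500 * 5), 500, 5) %*% chol(S)
  expect_lt(bartlett_sphericity(Xe)$p, 1e-10)
  expect_error(bartlett_sphericity(X[1:4, ]), "n > p")
})

test_that("PCA on the correlation matrix obeys its algebraic contracts", {
  set.seed(43)
  X <- matrix(rnorm(250 * 5), 250, 5)
  colnames(X) <- HABITAT_COVARIATES
  # near-duplicated covariates concentrate variance on PC1
  X[, 2] <- X[, 1] + rnorm(250, 0, 0.1)
  res <- pca_core(X)
  expect_gt(res$variance_explained[1] / 100, 2 / 5)
  expect_equal(sum(res$variance_explained), 100, tolerance = 1e-8)
  expect_equal(crossprod(res$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in 1:5)
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  # scores: zero mean, diagonal covariance with eigenvalue variances
  expect_lt(max(abs(colMeans(res$scores))), 1e-10)
  cs <- cov(res$scores)
  expect_lt(max(abs(cs - diag(diag(cs)))), 1e-8)

  grp <- rep(REPRO_CLASSES, length.out = 250)
  res2 <- pca_core(X, groups = grp)
  expect_equal(nrow(res2$group_summary), 6)  # 3 groups x PC1/PC2
  expect_true(all(res2$group_summary$ci_lo <= res2$group_summary$mean))

  Xdef <- X; Xdef[, 2] <- Xdef[, 1]
  expect_error(pca_core(Xdef), "rank")
})

test_that("class core means bootstrap matches closed-form standard errors", {
  cfg <- run_config(seed = 6, bootstrap_iterations = 600)
  tab <- make_label_table(200, seed = 21)
  got <- class_core_means(tab, cfg)
  expect_equal(nrow(got), 15)
  g <- got[got$class == "male" & got$covariate == "canopy", ]
  v <- tab$canopy[tab$class == "male"]
  expect_equal(g$mean, mean(v), tolerance = 0.05)
  expect_lt(abs(g$se - sd(v) / sqrt(length(v))) / (sd(v) / sqrt(length(v))),
            0.15)
  # constant column: zero SE
  tabc <- tab; tabc$rock <- 40
  gc <- class_core_means(tabc, cfg)
  expect_equal(gc$se[gc$covariate == "rock"], rep(0, 3))
  # seeded determinism
  expect_equal(class_core_means(tab, cfg), got)
  # absent class marked unavailable
  tab2 <- tab[tab$class != "male", ]
  g2 <- class_core_means(tab2, cfg)
  expect_true(all(is.na(g2$mean[g2$class == "male"])))
})
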