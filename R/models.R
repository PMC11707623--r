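# Level-specific resource-utilization models: standardized designs, VIF
# screening, logistic and random-intercept logistic fits, all-subsets full
# model averaging, the Wald cross-level contrast, and marginal-effect curves.

#' Build standardized design matrices for both levels
#'
#' z-score standardizes the five covariates once and returns two designs that
#' share the identical covariate matrix: the individual-level design
#' (response `core_ind`, no grouping; labels are season-relative, so a
#' season random effect would be meaningless) and the population-level
#' design (response `core_pop`, grouped by animal-season for the random
#' intercept).
#'
#' @param table a `core_labels` data frame with at least 50 rows.
#' @return list with elements `ind` and `pop`, each a `design_matrix`:
#'   `y` (binary), `X` (n x 5 standardized), `group` (factor or NULL),
#'   `names`.
#' @export
standardize <- function(table) {
  if (nrow(table) < 50) stop("standardize requires at least 50 observations")
  X <- as.matrix(as.data.frame(table)[HABITAT_COVARIATES])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance covariate(s): ",
         paste(HABITAT_COVARIATES[sds == 0], collapse = ", "))
  Z <- scale(X)
  attr(Z, "scaled:center") <- NULL; attr(Z, "scaled:scale") <- NULL
  design <- function(y, group) {
    structure(list(y = as.integer(y), X = Z, group = group,
                   names = HABITAT_COVARIATES), class = "design_matrix")
  }
  list(ind = design(table$core_ind, NULL),
       pop = design(table$core_pop,
                    factor(season_key(table$animal_id, table$season_id))))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate j on the others;
#' values at or above `vif_max` are flagged. Perfect collinearity yields an
#' infinite VIF with a warning rather than an error so screening can report
#' every column.
#'
#' @param design a `design_matrix` (or bare numeric matrix) with >= 2
#'   columns.
#' @param vif_max flag threshold.
#' @return data frame with columns covariate, vif, flagged.
#' @export
vif <- function(design, vif_max = 2.0) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (ncol(X) < 2) stop("vif requires at least 2 covariates")
  vals <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(!is.finite(vals)))
    warning("perfectly collinear covariate(s): ",
            paste(colnames(X)[!is.finite(vals)], collapse = ", "))
  data.frame(covariate = colnames(X), vif = vals, flagged = vals >= vif_max,
             row.names = NULL)
}

new_fitted_model <- function(terms, coef, se, logLik, k, extra = list()) {
  structure(c(list(terms = terms, coef = coef, se = se, logLik = logLik,
                   aic = 2 * k - 2 * logLik, k = k), extra),
            class = "fitted_model")
}

#' Logistic regression on a covariate subset
#'
#' Maximum-likelihood logit fit (IRLS) of the design's binary response on
#' the selected standardized covariates plus an intercept, with
#' observed-information standard errors.
#'
#' @param design a `design_matrix`.
#' @param terms character vector of covariate names to include (default all;
#'   empty gives the intercept-only model).
#' @return a `fitted_model`: terms, named coefficients and SEs (intercept
#'   first), log-likelihood, AIC, parameter count `k`.
#' @export
fit_logistic <- function(design, terms = design$names) {
  y <- design$y
  if (length(unique(y)) < 2) stop("response must contain both classes")
  X <- cbind(`(Intercept)` = 1, design$X[, terms, drop = FALSE])
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 100)))
  if (!fit$converged) stop("logistic fit did not converge in 100 iterations")
  beta <- fit$coefficients
  if (any(abs(beta[-1]) > 15))
    stop("apparent complete separation on term(s): ",
         paste(names(beta[-1])[abs(beta[-1]) > 15], collapse = ", "))
  covm <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(covm))
  names(se) <- names(beta)
  ll <- -fit$deviance / 2
  new_fitted_model(terms, beta, se, ll, k = length(beta))
}

#' Random-intercept logistic regression on a covariate subset
#'
#' Logistic model with a Gaussian random intercept per group (animal-season),
#' fitted by `lme4::glmer`. The default uses the Laplace approximation;
#' `nAGQ >= 9` selects adaptive Gauss-Hermite quadrature. `k` counts the
#' fixed effects, the intercept, and the random-intercept variance.
#'
#' @param design a `design_matrix` with a `group` factor of >= 5 levels.
#' @param terms covariate names to include.
#' @param nAGQ quadrature nodes (1 = Laplace).
#' @return a `fitted_model` with additional fields `re_variance` and
#'   `boundary` (TRUE when the variance estimate collapses to 0).
#' @export
fit_mixed_logistic <- function(design, terms = design$names, nAGQ = 1) {
  if (is.null(design$group)) stop("design has no grouping factor")
  if (nlevels(droplevels(factor(design$group))) < 5)
    stop("mixed logistic requires at least 5 groups")
  if (length(unique(design$y)) < 2) stop("response must contain both classes")
  df <- data.frame(.y = design$y, .grp = factor(design$group))
  df[design$names] <- as.data.frame(design$X)
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .grp)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = df, family = stats::binomial(), nAGQ = nAGQ)))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  names(se) <- names(beta)
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_var <- vc$vcov[1]
  ll <- as.numeric(stats::logLik(fit))
  k <- length(beta) + 1L
  new_fitted_model(terms, beta, se, ll, k,
                   extra = list(re_variance = re_var,
                                boundary = re_var < 1e-6))
}

# Full model averaging across a candidate list under a dAIC cutoff.
# A covariate absent from a model contributes beta = 0 and SE = 0; the
# unconditional SE follows the model-averaging formula
#   SE_j = sum_m w_m * sqrt(SE_mj^2 + (beta_mj - beta_bar_j)^2).
average_fits <- function(fits, covariates, cut) {
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  delta <- aics - min(aics)
  in_set <- delta < cut
  w <- exp(-delta / 2) * in_set
  w <- w / sum(w)
  all_terms <- c("(Intercept)", covariates)
  B <- SE <- matrix(0, length(fits), length(all_terms),
                    dimnames = list(NULL, all_terms))
  for (m in seq_along(fits)) {
    B[m, names(fits[[m]]$coef)] <- fits[[m]]$coef
    SE[m, names(fits[[m]]$se)] <- fits[[m]]$se
  }
  beta_bar <- as.vector(w %*% B)
  names(beta_bar) <- all_terms
  se_bar <- vapply(seq_along(all_terms), function(j)
    sum(w * sqrt(SE[, j]^2 + (B[, j] - beta_bar[j])^2)), numeric(1))
  names(se_bar) <- all_terms
  ledger <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = "+") else "(null)",
      character(1)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    aic = aics, delta_aic = delta, weight = w, in_set = in_set,
    row.names = NULL)
  coef_table <- data.frame(
    term = all_terms, estimate = beta_bar, se = se_bar,
    ci_lo = beta_bar - 1.96 * se_bar, ci_hi = beta_bar + 1.96 * se_bar,
    row.names = NULL)
  structure(list(coefficients = coef_table, ledger = ledger,
                 covariates = covariates),
            class = "averaged_model")
}

#' All-subsets full model averaging
#'
#' Fits every combination of the five covariates (32 candidate models, the
#' intercept -- and, when `mixed`, the random intercept -- always included),
#' ranks them by AIC, and computes full model averages over the candidates
#' within `delta_aic_cut` of the best model: Akaike weights renormalized
#' within the set, covariates absent from a model contributing zero to its
#' average, and unconditional SEs combining within-model variance and
#' between-model spread. 95% CIs are Wald (+/- 1.96 SE).
#'
#' @param design a `design_matrix`.
#' @param mixed fit [fit_mixed_logistic()] (population level) instead of
#'   [fit_logistic()].
#' @param cfg a [run_config()] (uses `delta_aic_cut`).
#' @return an `averaged_model`: a coefficient table (term, estimate,
#'   unconditional SE, CI) and the full 32-model ledger (terms, AIC, ΔAIC,
#'   Akaike weight, in/out of the averaging set).
#' @export
all_subsets_average <- function(design, mixed = FALSE, cfg = run_config()) {
  covs <- design$names
  subsets <- unlist(lapply(0:length(covs), function(k)
    utils::combn(covs, k, simplify = FALSE)), recursive = FALSE)
  fitter <- if (mixed) fit_mixed_logistic else fit_logistic
  fits <- list(); failed <- character()
  for (s in subsets) {
    f <- tryCatch(fitter(design, s), error = function(e) e)
    if (inherits(f, "error")) {
      failed <- c(failed, paste(s, collapse = "+"))
    } else fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) stop("every candidate model failed to fit")
  if (length(failed))
    warning("excluded candidate model(s) that failed to fit: ",
            paste(failed, collapse = "; "))
  average_fits(fits, covs, cfg$delta_aic_cut)
}

#' Wald chi-square contrast of covariate effects across levels
#'
#' Tests, per covariate, whether the model-averaged individual-level and
#' population-level coefficients differ:
#' `W = (b_ind - b_pop)^2 / (SE_ind^2 + SE_pop^2)`, compared to chi-square
#' with 1 df. The two averaged coefficients are treated as independent (the
#' two labelings come from different UD constructions; no cross-level
#' covariance is estimated).
#'
#' @param ind,pop `averaged_model`s over the same covariate set.
#' @return a `level_contrast` data frame: per covariate, both estimates and
#'   CIs, Wald `W`, df (1), and p.
#' @export
wald_level_test <- function(ind, pop) {
  if (!identical(ind$covariates, pop$covariates))
    stop("averaged models cover different covariate sets")
  ci <- ind$coefficients; cp <- pop$coefficients
  sel <- ci$term != "(Intercept)"
  ci <- ci[sel, ]; cp <- cp[cp$term != "(Intercept)", ]
  if (any(ci$se == 0) || any(cp$se == 0))
    stop("zero standard error; Wald contrast undefined")
  W <- (ci$estimate - cp$estimate)^2 / (ci$se^2 + cp$se^2)
  structure(data.frame(
    covariate = ci$term,
    beta_ind = ci$estimate, ci_lo_ind = ci$ci_lo, ci_hi_ind = ci$ci_hi,
    beta_pop = cp$estimate, ci_lo_pop = cp$ci_lo, ci_hi_pop = cp$ci_hi,
    W = W, df = 1L, p = stats::pchisq(W, df = 1, lower.tail = FALSE),
    row.names = NULL), class = c("level_contrast", "data.frame"))
}

#' Marginal-effect curve of one covariate
#'
#' Predicted core-membership probability over a grid of standardized
#' covariate values with all other covariates held at 0 (their standardized
#' mean), with a 95% delta-method CI built on the linear predictor and
#' mapped through the inverse logit.
#'
#' @param avg an `averaged_model`.
#' @param covariate covariate name.
#' @param grid standardized covariate values; values beyond +/- 3 SD trigger
#'   a warning.
#' @return data frame with columns value, prob, ci_lo, ci_hi.
#' @export
marginal_effects <- function(avg, covariate,
                             grid = seq(-3, 3, length.out = 61)) {
  co <- avg$coefficients
  if (!covariate %in% co$term) stop("covariate not in model: ", covariate)
  if (any(abs(grid) > 3))
    warning("grid extends beyond +/- 3 standardized units")
  b0 <- co$estimate[co$term == "(Intercept)"]
  s0 <- co$se[co$term == "(Intercept)"]
  bj <- co$estimate[co$term == covariate]
  sj <- co$se[co$term == covariate]
  eta <- b0 + bj * grid
  se_eta <- sqrt(s0^2 + grid^2 * sj^2)
  data.frame(value = grid, prob = stats::plogis(eta),
             ci_lo = stats::plogis(eta - 1.96 * se_eta),
             ci_hi = stats::plogis(eta + 1.96 * se_eta))
}
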