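# Core-area habitat comparison by reproductive class and by ecological
# level: multinomial logit, pairwise estimated-marginal-mean contrasts,
# Bartlett's sphericity test, PCA with the |0.5| loading rule, and
# bootstrap class summaries.

# Rows for the two multinomial models.  "class": observations core at the
# individual level, grouped by reproductive class.  "level": each
# observation contributes one row per level at which it is core (a point
# core at both levels appears twice), labeled individual/population.
multinomial_rows <- function(table, grouping) {
  if (grouping == "class") {
    rows <- table[table$core_ind == 1, , drop = FALSE]
    rows$group <- factor(rows$class, levels = REPRO_CLASSES)
    rows
  } else {
    ind <- table[table$core_ind == 1, , drop = FALSE]
    pop <- table[table$core_pop == 1, , drop = FALSE]
    if (nrow(ind)) ind$group <- "individual"
    if (nrow(pop)) pop$group <- "population"
    rows <- rbind(ind, pop)
    rows$group <- factor(rows$group, levels = c("individual", "population"))
    rows
  }
}

#' Multinomial logistic regression of core habitat composition
#'
#' Fits group membership (reproductive class, or ecological level) on the
#' five habitat covariates, standardized within the analysis rows.
#' Coefficients are effects on the log-odds of membership relative to the
#' reference group (gravid females for the class model, the individual level
#' for the level model).
#'
#' @param table a `core_labels` data frame.
#' @param grouping `"class"` or `"level"`.
#' @param reference reference group; defaults to `"gravid_female"` /
#'   `"individual"`.
#' @return a `multinom_fit`: reference, groups, coefficient and SE matrices
#'   (one row per non-reference group), the coefficient vcov, fitted
#'   probabilities, log-likelihood, and the analysis rows.
#' @export
fit_multinomial <- function(table, grouping = c("class", "level"),
                            reference = NULL) {
  grouping <- match.arg(grouping)
  if (is.null(reference))
    reference <- if (grouping == "class") "gravid_female" else "individual"
  rows <- multinomial_rows(table, grouping)
  rows <- droplevels(rows[!is.na(rows$group), , drop = FALSE])
  tab <- table(rows$group)
  if (length(tab) < 2) stop("fewer than 2 groups present")
  if (any(tab < 10))
    stop("group(s) with fewer than 10 core rows: ",
         paste(names(tab)[tab < 10], collapse = ", "))
  rows$group <- stats::relevel(rows$group, ref = reference)
  Z <- scale(as.matrix(rows[HABITAT_COVARIATES]))
  d <- data.frame(group = rows$group)
  d[HABITAT_COVARIATES] <- as.data.frame(Z)
  form <- stats::as.formula(paste("group ~",
                                  paste(HABITAT_COVARIATES, collapse = " + ")))
  fit <- nnet::multinom(form, data = d, trace = FALSE, maxit = 1000,
                        reltol = 1e-14, Hess = TRUE)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                     dimnames = list(levels(d$group)[2],
                                                     names(cf)))
  if (any(abs(cf[, -1]) > 15))
    stop("apparent separation in multinomial fit")
  V <- tryCatch(solve(fit$Hessian), error = function(e)
    stop("singular information matrix in multinomial fit"))
  npar <- ncol(cf)
  se <- matrix(sqrt(diag(V)), nrow = nrow(cf), ncol = npar, byrow = TRUE,
               dimnames = dimnames(cf))
  probs <- stats::fitted(fit)
  if (is.null(dim(probs))) probs <- as.matrix(probs)
  if (ncol(probs) == 1) probs <- cbind(1 - probs[, 1], probs[, 1])
  structure(list(grouping = grouping, reference = reference,
                 groups = levels(d$group), coef = cf, se = se, vcov = V,
                 fitted = probs, logLik = as.numeric(stats::logLik(fit)),
                 n = nrow(d), rows = d),
            class = "multinom_fit")
}

#' Pairwise estimated-marginal-mean contrasts
#'
#' Evaluates each group's marginal (latent-scale) log-odds of membership at
#' the average of the predictors -- the zero vector under standardization --
#' and tests all pairwise differences with delta-method SEs from the
#' multinomial information matrix and a normal reference distribution.
#' Latent means are centered across groups (as in emmeans' latent mode);
#' centering cancels in the differences.
#'
#' @param fit a `multinom_fit`.
#' @return list with `emmeans` (group, latent marginal mean) and `contrasts`
#'   (pair, difference, SE, z, p, significant at 0.05).
#' @export
emm_pairwise <- function(fit) {
  G <- length(fit$groups)
  npar <- ncol(fit$coef)
  # latent log-odds at x = 0: the intercepts, with 0 for the reference
  eta <- c(0, fit$coef[, "(Intercept)"])
  names(eta) <- fit$groups
  # vcov of the intercepts (parameter order: group-major within rows of coef)
  int_idx <- (seq_len(G - 1) - 1) * npar + 1
  Vi <- fit$vcov[int_idx, int_idx, drop = FALSE]
  emms <- eta - mean(eta)
  pairs <- utils::combn(fit$groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- match(pr[1], fit$groups) - 1L   # 0 = reference
    b <- match(pr[2], fit$groups) - 1L
    v <- numeric(G - 1)
    if (a > 0) v[a] <- v[a] + 1
    if (b > 0) v[b] <- v[b] - 1
    d <- eta[pr[1]] - eta[pr[2]]
    se <- sqrt(as.numeric(t(v) %*% Vi %*% v))
    z <- d / se
    data.frame(contrast = paste(pr[1], "-", pr[2]), difference = d, se = se,
               z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  contrasts <- do.call(rbind, c(rows, make.row.names = FALSE))
  contrasts$significant <- contrasts$p < 0.05
  list(emmeans = data.frame(group = fit$groups, latent_mean = emms,
                            row.names = NULL),
       contrasts = contrasts)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the covariate correlation matrix departs from identity
#' (a precondition check before PCA):
#' `chi^2 = -(n - 1 - (2p + 5)/6) * ln|R|`, df = p(p-1)/2.
#'
#' @param X numeric matrix (n > p columns).
#' @return list with `chisq`, `df`, `p`.
#' @export
bartlett_sphericity <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("bartlett_sphericity requires n > p")
  R <- stats::cor(X)
  dR <- det(R)
  if (dR <= 0) stop("correlation matrix is numerically singular")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(dR)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' PCA of core-area habitat composition
#'
#' Eigendecomposition of the covariate correlation matrix over core
#' observations, with Bartlett's sphericity test reported alongside.
#' Loadings are sign-normalized (largest-magnitude element of each component
#' positive) so output is deterministic across linear-algebra backends.
#' Loadings with magnitude >= 0.5 are flagged strong; covariate-component
#' correlations are flagged at r > 0.40.
#'
#' @param X n x 5 covariate matrix (core rows, raw percent scale).
#' @param groups optional factor (length n) for per-group score summaries.
#' @return a `pca_result`: orthonormal `loadings`, `variance_explained`
#'   (percent, sums to 100), `scores`, `strong_loadings`, `correlations` and
#'   `strong_correlations`, the Bartlett test, and per-group mean/SE/95% CI
#'   of PC1 and PC2 scores.
#' @export
pca_core <- function(X, groups = NULL) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("pca_core requires n > p")
  if (qr(scale(X))$rank < ncol(X)) stop("covariate matrix is rank-deficient")
  bart <- bartlett_sphericity(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  L <- eig$vectors
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(ncol(L)))
  scores <- scale(X) %*% L
  var_exp <- 100 * eig$values / sum(eig$values)
  cors <- stats::cor(X, scores)
  group_summary <- NULL
  if (!is.null(groups)) {
    groups <- factor(groups)
    group_summary <- do.call(rbind, lapply(levels(groups), function(g) {
      do.call(rbind, lapply(1:2, function(pc) {
        v <- scores[groups == g, pc]
        se <- stats::sd(v) / sqrt(length(v))
        data.frame(group = g, component = paste0("PC", pc), n = length(v),
                   mean = mean(v), se = se,
                   ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se)
      }))
    }))
  }
  structure(list(loadings = L, variance_explained = var_exp, scores = scores,
                 strong_loadings = abs(L) >= 0.5,
                 correlations = cors, strong_correlations = abs(cors) > 0.40,
                 bartlett = bart, group_summary = group_summary),
            class = "pca_result")
}

#' Bootstrap core-habitat means by reproductive class
#'
#' Per class and covariate: bootstrap mean, SE and 95% percentile CI of
#' covariate values among individual-level core observations.
#'
#' @param table a `core_labels` data frame.
#' @param cfg a [run_config()].
#' @return data frame with class, covariate, n, mean, se, ci_lo, ci_hi;
#'   classes with no core rows are marked unavailable (`NA`s).
#' @export
class_core_means <- function(table, cfg) {
  core <- table[table$core_ind == 1, , drop = FALSE]
  with_seed(child_seed(cfg$seed, "class_core_means"), {
    rows <- list()
    for (cls in REPRO_CLASSES) {
      sel <- core$class == cls
      for (v in HABITAT_COVARIATES) {
        bc <- boot_mean_ci(core[[v]][sel], cfg$bootstrap_iterations)
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, covariate = v, n = sum(sel),
          mean = bc[["mean"]], se = bc[["se"]],
          ci_lo = bc[["lo"]], ci_hi = bc[["hi"]])
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}
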