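# Empirical semivariograms of habitat covariates at relocation points.

#' Empirical (omnidirectional) semivariogram
#'
#' `gamma(h) = (1 / (2 N(h))) * sum over pairs in bin h of (z_i - z_j)^2`
#' on equal-width distance bins over (0, max_lag]. Used to confirm and
#' quantify spatial autocorrelation in the habitat covariates; no variogram
#' model is fitted.
#'
#' @param x,y point coordinates (>= 30 points).
#' @param values covariate values at the points.
#' @param n_bins number of lag bins.
#' @param max_lag maximum lag (m); defaults to half the maximum pairwise
#'   distance.
#' @return a `semivariogram` data frame: bin center `lag`, `gamma`
#'   (`NA` for empty bins), and pair count `n_pairs`; attribute `max_lag`.
#' @export
empirical_semivariogram <- function(x, y, values, n_bins = 15,
                                    max_lag = NULL) {
  n <- length(x)
  if (n < 2) stop("semivariogram requires at least 2 points")
  if (n < 30)
    warning("fewer than 30 points; semivariogram estimates will be noisy")
  stopifnot(length(y) == n, length(values) == n)
  d <- stats::dist(cbind(x, y))
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (max_lag > max(d)) stop("max_lag exceeds the maximum pairwise distance")
  dv <- stats::dist(matrix(values, ncol = 1))^2
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- findInterval(as.vector(d), breaks, left.open = TRUE,
                      rightmost.closed = FALSE)
  keep <- bin >= 1 & bin <= n_bins & as.vector(d) > 0
  bin <- bin[keep]; dv <- as.vector(dv)[keep]
  n_pairs <- tabulate(bin, nbins = n_bins)
  ssq <- vapply(seq_len(n_bins), function(b) sum(dv[bin == b]), numeric(1))
  gamma <- ifelse(n_pairs > 0, ssq / (2 * n_pairs), NA_real_)
  structure(data.frame(lag = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
                       gamma = gamma, n_pairs = n_pairs),
            max_lag = max_lag,
            class = c("semivariogram", "data.frame"))
}

#' Semivariograms of all habitat covariates at relocations
#'
#' @param data a telemetry data frame.
#' @param n_bins,max_lag passed to [empirical_semivariogram()].
#' @return long-format data frame (covariate, lag, gamma, n_pairs).
#' @export
covariate_semivariograms <- function(data, n_bins = 15, max_lag = NULL) {
  do.call(rbind, lapply(HABITAT_COVARIATES, function(v) {
    sv <- empirical_semivariogram(data$x, data$y, data[[v]],
                                  n_bins = n_bins, max_lag = max_lag)
    cbind(covariate = v, as.data.frame(sv))
  }))
}
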