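# Dual core/noncore labeling of relocations from the 30% volume contours of
# the season UD and the population UD.

#' Label observations by core-area membership at both levels
#'
#' Each retained relocation receives two binary use-intensity labels:
#' `core_ind` is 1 when the relocation's cell belongs to the 30% (or
#' `core_isopleth`) volume contour of its own season's UD, and `core_pop`
#' likewise on the population UD. Membership is decided by cell index, never
#' by polygonized contour geometry, so boundary points are unambiguous.
#'
#' @param data a filtered telemetry data frame.
#' @param ind_uds named list of season UDs from [individual_uds()].
#' @param pop_ud population UD from [population_ud()]; must cover all points.
#' @param cfg a [run_config()].
#' @return a `core_labels` data frame: observation identifiers, class, the
#'   five covariates, and `core_ind`/`core_pop` in {0, 1}.
#' @export
label_observations <- function(data, ind_uds, pop_ud, cfg) {
  key <- season_key(data$animal_id, data$season_id)
  missing_ud <- setdiff(unique(key), names(ind_uds))
  if (length(missing_ud))
    stop("no individual UD for season(s): ", paste(missing_ud, collapse = ", "))
  pop_core <- volume_contour(pop_ud, cfg$core_isopleth)
  pop_members <- logical(pop_ud$grid$nrows * pop_ud$grid$ncols)
  pop_members[pop_core$cells] <- TRUE
  core_ind <- integer(nrow(data)); core_pop <- integer(nrow(data))
  for (sk in unique(key)) {
    rows <- which(key == sk)
    ud <- ind_uds[[sk]]
    contour <- volume_contour(ud, cfg$core_isopleth)
    members <- logical(ud$grid$nrows * ud$grid$ncols)
    members[contour$cells] <- TRUE
    cells <- point_to_cell(ud$grid, data$x[rows], data$y[rows])
    if (anyNA(cells$index))
      stop("observation(s) outside the season UD grid: obs_id ",
           paste(data$obs_id[rows][is.na(cells$index)], collapse = ", "))
    core_ind[rows] <- as.integer(members[cells$index])
  }
  pcells <- point_to_cell(pop_ud$grid, data$x, data$y)
  if (anyNA(pcells$index))
    stop("observation(s) outside the population UD grid: obs_id ",
         paste(data$obs_id[is.na(pcells$index)], collapse = ", "))
  core_pop <- as.integer(pop_members[pcells$index])
  out <- data.frame(obs_id = data$obs_id, animal_id = data$animal_id,
                    season_id = data$season_id, class = data$class,
                    stringsAsFactors = FALSE)
  out[HABITAT_COVARIATES] <- as.data.frame(data)[HABITAT_COVARIATES]
  out$core_ind <- core_ind
  out$core_pop <- core_pop
  structure(out, class = c("core_labels", "data.frame"))
}

# seeded percentile bootstrap of a mean
boot_mean_ci <- function(v, n_iter, conf = 0.95) {
  if (!length(v)) return(c(mean = NA_real_, se = NA_real_,
                           lo = NA_real_, hi = NA_real_))
  means <- vapply(seq_len(n_iter), function(i)
    mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
  q <- stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE, type = 7)
  c(mean = mean(means), se = stats::sd(means), lo = q[1], hi = q[2])
}

#' Bootstrap summaries of core-area habitat conditions
#'
#' For each level (individual, population) and covariate, the bootstrap mean
#' and 95% percentile interval of covariate values among core observations.
#' Percentile bootstrap is used because the covariates are bounded and
#' non-normal.
#'
#' @param table a `core_labels` data frame.
#' @param cfg a [run_config()]; `bootstrap_iterations` and `seed` control the
#'   resampling.
#' @return data frame with columns level, covariate, n, mean, se, ci_lo,
#'   ci_hi; a level with no core rows is marked unavailable (`NA`s).
#' @export
core_summaries <- function(table, cfg) {
  stopifnot(nrow(table) > 0)
  with_seed(child_seed(cfg$seed, "core_summaries"), {
    rows <- list()
    for (level in c("individual", "population")) {
      sel <- if (level == "individual") table$core_ind == 1 else
        table$core_pop == 1
      for (v in HABITAT_COVARIATES) {
        bc <- boot_mean_ci(table[[v]][sel], cfg$bootstrap_iterations)
        rows[[length(rows) + 1L]] <- data.frame(
          level = level, covariate = v, n = sum(sel),
          mean = bc[["mean"]], se = bc[["se"]],
          ci_lo = bc[["lo"]], ci_hi = bc[["hi"]])
      }
    }
    do.call(rbind, rows)
  })
}
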