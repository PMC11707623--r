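# Kernel utilization distributions with MCP-area-matched bandwidth tuning,
# volume contours, and individual- and population-level UD construction.

#' Kernel density utilization distribution
#'
#' Evaluates a bivariate Gaussian kernel density (equal bandwidth in x and y)
#' at every cell center and renormalizes so the density integrates to 1 over
#' the grid. The kernel is truncated at 5 standard deviations (mass error
#' < 1e-6) so the evaluation is a pair of banded matrix products.
#'
#' @param x,y relocation coordinates (m); all points must fall inside the
#'   grid. A margin of at least 3 bandwidths around the points keeps edge
#'   truncation negligible before renormalization.
#' @param bandwidth kernel standard deviation (m).
#' @param grid a [grid_spec()].
#' @param source optional provenance tag (`level`, `ids`).
#' @return an object of class `ud_raster`: the grid, a `nrows x ncols`
#'   density matrix (rows south-first, per-m^2 density), and the bandwidth.
#' @export
kde_ud <- function(x, y, bandwidth, grid,
                   source = list(level = NA_character_, ids = character())) {
  if (length(x) < 1) stop("kde_ud requires at least one point")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  xmax <- grid$xll + grid$ncols * grid$cellsize
  ymax <- grid$yll + grid$nrows * grid$cellsize
  if (any(x < grid$xll | x > xmax | y < grid$yll | y > ymax))
    stop("grid does not cover all points")
  cc <- cell_centers(grid)
  dx <- outer(cc$x, x, "-") / bandwidth
  dy <- outer(cc$y, y, "-") / bandwidth
  kx <- exp(-0.5 * dx * dx); kx[abs(dx) > 5] <- 0
  ky <- exp(-0.5 * dy * dy); ky[abs(dy) > 5] <- 0
  dens <- tcrossprod(ky, kx)             # nrows x ncols
  total <- sum(dens) * grid$cellsize^2
  if (total <= 0) stop("degenerate density (no kernel mass on grid)")
  structure(list(grid = grid, density = dens / total, bandwidth = bandwidth,
                 source = source),
            class = "ud_raster")
}

#' Total probability mass of a UD raster
#' @param ud a `ud_raster`.
#' @return sum of density times cell area (1 for a normalized UD).
#' @export
ud_mass <- function(ud) sum(ud$density) * ud$grid$cellsize^2

#' Volume contour (isopleth) of a utilization distribution
#'
#' Sorts cells by density, descending, with ties broken by row-major cell
#' index, and takes the shortest prefix whose cumulative mass reaches the
#' isopleth. This is the minimal-area region containing the requested
#' fraction of the UD's volume under the declared tie rule.
#'
#' @param ud a normalized `ud_raster`.
#' @param isopleth volume fraction in (0, 1).
#' @return an object of class `cell_set`: the grid, member cell indices
#'   (row-major, 1-based), the isopleth, and the region area in m^2.
#' @export
volume_contour <- function(ud, isopleth) {
  if (isopleth <= 0 || isopleth >= 1) stop("isopleth must be in (0, 1)")
  if (abs(ud_mass(ud) - 1) > 1e-6) stop("UD is not normalized")
  dens_rm <- as.vector(t(ud$density))    # row-major order
  ord <- order(-dens_rm, seq_along(dens_rm))
  cum <- cumsum(dens_rm[ord]) * ud$grid$cellsize^2
  k <- which(cum >= isopleth - 1e-12)[1]
  members <- ord[seq_len(k)]
  structure(list(grid = ud$grid, cells = members, isopleth = isopleth,
                 area = k * ud$grid$cellsize^2),
            class = "cell_set")
}

#' Tune the KDE bandwidth to match a home-range area
#'
#' Walks the bandwidth up from `h0` in increments of `step` and returns the
#' first bandwidth whose 95% (or `outer_isopleth`) volume-contour area
#' reaches `target_area` -- the area-matching rule that anchors the UD's
#' spatial scale to the MCP home range. Exact equality is unattainable on a
#' discrete raster, so the first crossing on the step grid is used; because
#' contour area is non-decreasing in bandwidth, the result does not depend on
#' the starting point, and a warm start (e.g. the previous resampling
#' iteration's bandwidth) only saves evaluations.
#'
#' @param x,y point coordinates.
#' @param target_area target area in m^2 (e.g. the 95% MCP area).
#' @param grid fixed evaluation grid (fixed before tuning so area
#'   comparisons are grid-consistent).
#' @param h0 smallest candidate bandwidth (m); defaults to `step`.
#' @param step bandwidth increment (m).
#' @param h_max cap on the candidate bandwidth.
#' @param outer_isopleth volume fraction matched against `target_area`.
#' @param warm_start optional bandwidth on the same step grid to start from.
#' @return list with `bandwidth`, the matching `ud`, and a `trace` data frame
#'   of evaluated (h, area) pairs.
#' @export
tune_bandwidth <- function(x, y, target_area, grid, h0 = NULL, step = 1,
                           h_max = 500, outer_isopleth = 0.95,
                           warm_start = NULL) {
  if (target_area <= 0) stop("target_area must be > 0")
  if (step <= 0) stop("step must be > 0")
  if (is.null(h0)) h0 <- step
  if (h0 <= 0) stop("h0 must be > 0")
  cache <- new.env(parent = emptyenv())
  trace <- list()
  eval_h <- function(h) {
    key <- format(h, digits = 15)
    if (!is.null(cache[[key]])) return(cache[[key]])
    ud <- kde_ud(x, y, h, grid)
    a <- volume_contour(ud, outer_isopleth)$area
    res <- list(h = h, area = a, ud = ud)
    cache[[key]] <- res
    trace[[length(trace) + 1L]] <<- data.frame(h = h, area = a)
    res
  }
  on_grid <- function(k) h0 + k * step
  k <- 0L
  if (!is.null(warm_start) && warm_start > h0)
    k <- max(0L, as.integer(round((warm_start - h0) / step)))
  res <- eval_h(on_grid(k))
  if (res$area >= target_area) {
    # walk down to the first crossing
    while (k > 0L) {
      below <- eval_h(on_grid(k - 1L))
      if (below$area >= target_area) { k <- k - 1L; res <- below }
      else break
    }
  } else {
    repeat {
      k <- k + 1L
      if (on_grid(k) > h_max) {
        tr <- do.call(rbind, trace)
        stop("bandwidth tuning failed to reach target area ",
             format(target_area), " below h_max = ", h_max,
             " (last area ", format(max(tr$area)), ")")
      }
      res <- eval_h(on_grid(k))
      if (res$area >= target_area) break
    }
  }
  tr <- do.call(rbind, trace)
  tr <- tr[order(tr$h), , drop = FALSE]
  list(bandwidth = res$h, ud = res$ud, trace = tr)
}

#' Individual (per-season) utilization distributions
#'
#' For each animal-season: computes the 95% MCP area of the season's
#' relocations, then tunes the KDE bandwidth so the 95% volume contour of
#' the season UD matches that area, on a season-specific grid (season extent
#' plus margin).
#'
#' @param data a filtered telemetry data frame.
#' @param cfg a [run_config()].
#' @return named list of `ud_raster`s by [season_key()]; attribute `tuning`
#'   is a data frame of (season, bandwidth, contour area, target area).
#' @export
individual_uds <- function(data, cfg) {
  key <- season_key(data$animal_id, data$season_id)
  out <- list(); tune_rows <- list()
  for (sk in unique(key)) {
    pts <- data[key == sk, , drop = FALSE]
    target <- mcp(pts, cfg$mcp_percent)$area
    grid <- grid_for_points(pts$x, pts$y, cfg$grid_cell, cfg$grid_margin)
    tuned <- tune_bandwidth(pts$x, pts$y, target, grid,
                            step = cfg$bandwidth_step, h_max = cfg$h_max,
                            outer_isopleth = cfg$outer_isopleth)
    tuned$ud$source <- list(level = "individual", ids = sk)
    out[[sk]] <- tuned$ud
    tune_rows[[sk]] <- data.frame(
      season = sk, bandwidth = tuned$bandwidth,
      contour_area = tuned$trace$area[tuned$trace$h == tuned$bandwidth],
      target_area = target)
  }
  structure(out, tuning = do.call(rbind, c(tune_rows, make.row.names = FALSE)))
}

#' Resampling-averaged population utilization distribution
#'
#' Controls for unequal tracking durations by repeated random sampling: on
#' each iteration one season is drawn per animal, the selected seasons'
#' relocations are pooled, a 95% MCP is computed from the pooled points, the
#' bandwidth is tuned to its area, and the UD is evaluated on a fixed
#' population grid (all-data extent plus margin). The cellwise mean over
#' iterations, renormalized, is the population UD.
#'
#' @param data a filtered telemetry data frame with at least 2 animals.
#' @param cfg a [run_config()]; `pop_ud_iterations` and `seed` control the
#'   resampling.
#' @param grid optional fixed grid; defaults to the all-data extent plus
#'   `grid_margin`.
#' @return a `ud_raster` (level "population"); attribute `bandwidths` holds
#'   the per-iteration tuned bandwidths.
#' @export
population_ud <- function(data, cfg, grid = NULL) {
  if (length(unique(data$animal_id)) < 2)
    stop("population UD requires at least 2 animals")
  key <- season_key(data$animal_id, data$season_id)
  seasons_by_animal <- split(unique(key),
                             sub("\\|.*$", "", unique(key)))
  if (any(lengths(seasons_by_animal) == 0))
    stop("an animal has no retained seasons")
  if (is.null(grid))
    grid <- grid_for_points(data$x, data$y, cfg$grid_cell, cfg$grid_margin)
  rows_by_season <- split(seq_len(nrow(data)), key)
  acc <- matrix(0, grid$nrows, grid$ncols)
  bandwidths <- numeric(cfg$pop_ud_iterations)
  with_seed(child_seed(cfg$seed, "population_ud"), {
    warm <- NULL
    for (it in seq_len(cfg$pop_ud_iterations)) {
      picked <- vapply(seasons_by_animal, function(sks)
        if (length(sks) == 1) sks else sample(sks, 1), character(1))
      rows <- unlist(rows_by_season[picked], use.names = FALSE)
      pool <- data[rows, , drop = FALSE]
      target <- mcp(pool, cfg$mcp_percent)$area
      tuned <- tune_bandwidth(pool$x, pool$y, target, grid,
                              step = cfg$bandwidth_step, h_max = cfg$h_max,
                              outer_isopleth = cfg$outer_isopleth,
                              warm_start = warm)
      warm <- tuned$bandwidth
      bandwidths[it] <- tuned$bandwidth
      acc <- acc + tuned$ud$density
    }
  })
  avg <- acc / cfg$pop_ud_iterations
  avg <- avg / (sum(avg) * grid$cellsize^2)
  structure(list(grid = grid, density = avg,
                 bandwidth = stats::median(bandwidths),
                 source = list(level = "population",
                               ids = sort(unique(data$animal_id)))),
            class = "ud_raster", bandwidths = bandwidths)
}
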