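# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A reduced study: 6 animals / 9 seasons on a 400 m landscape.  Big enough
# for every pipeline stage, small enough to rebuild in seconds.
small_sim_config <- function(seed = 42) {
  sim_config(seed = seed, n_animals = 6, n_seasons = 9, extent = 400,
             n_meadows = 4)
}

small_run <- function() {
  if (!is.null(.fixtures$small_run)) return(.fixtures$small_run)
  cfg <- small_sim_config()
  land <- generate_landscape(cfg)
  tel <- simulate_telemetry(cfg, land)
  rc <- run_config(seed = 42, pop_ud_iterations = 10,
                   bootstrap_iterations = 200)
  tel_f <- filter_seasons(tel, rc$min_obs_per_season)
  uds <- individual_uds(tel_f, rc)
  pud <- population_ud(tel_f, rc)
  labels <- label_observations(tel_f, uds, pud, rc)
  .fixtures$small_run <- list(cfg = cfg, land = land, tel = tel_f, rc = rc,
                              uds = uds, pud = pud, labels = labels)
  .fixtures$small_run
}

# hand-built telemetry rows (planar coords well outside the geographic
# envelope so validation accepts them)
toy_telemetry <- function(n = 6, seed = 1) {
  with_seed(seed, {
    df <- data.frame(
      obs_id = seq_len(n),
      animal_id = rep(c("A1", "A2"), length.out = n),
      season_id = "s1",
      class = rep(REPRO_CLASSES, length.out = n),
      timestamp = as.character(as.Date("2018-05-01") + seq_len(n)),
      x = runif(n, 0, 500), y = runif(n, 0, 500),
      stringsAsFactors = FALSE)
    for (v in HABITAT_COVARIATES) df[[v]] <- runif(n, 10, 90)
    df
  })
}

# random normalized UD on a small grid (optionally with ties)
random_ud <- function(nrows, ncols, seed, ties = FALSE) {
  with_seed(seed, {
    g <- grid_spec(0, 0, 1, nrows, ncols)
    d <- matrix(stats::rexp(nrows * ncols), nrows, ncols)
    if (ties) {
      d <- matrix(sample(1:4, nrows * ncols, replace = TRUE), nrows, ncols)
    }
    d <- d / (sum(d) * g$cellsize^2)
    structure(list(grid = g, density = d, bandwidth = 1,
                   source = list(level = "individual", ids = "toy")),
              class = "ud_raster")
  })
}

# independent oracle: minimal prefix of cells by (density desc, row-major
# index) reaching the isopleth mass
oracle_contour <- function(ud, isopleth) {
  dens <- as.vector(t(ud$density))
  ord <- order(-dens, seq_along(dens))
  cum <- cumsum(dens[ord]) * ud$grid$cellsize^2
  k <- which(cum >= isopleth - 1e-12)[1]
  ord[seq_len(k)]
}

# design matrix with planted logistic structure (bypassing the UD stages)
make_design <- function(n, beta, seed, sigma_u = 0, n_groups = 25,
                        intercept = 0, X = NULL) {
  with_seed(seed, {
    if (is.null(X)) {
      X <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(NULL, HABITAT_COVARIATES))
      X <- scale(X)
    }
    group <- factor(rep_len(seq_len(n_groups), n))
    eta <- intercept + as.vector(X %*% beta)
    if (sigma_u > 0) eta <- eta + rnorm(n_groups, 0, sigma_u)[group]
    y <- rbinom(n, 1, plogis(eta))
    structure(list(y = y, X = X, group = group, names = colnames(X)),
              class = "design_matrix")
  })
}

# fraction of cell-set cells inside a circular zone
cells_in_zone <- function(cells, grid, center, radius) {
  cc <- cell_centers(grid)
  ri <- (cells - 1) %/% grid$ncols + 1
  cj <- (cells - 1) %% grid$ncols + 1
  (cc$x[cj] - center[["x"]])^2 + (cc$y[ri] - center[["y"]])^2 <= radius^2
}
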