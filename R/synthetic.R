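# Synthetic covariate landscapes and telemetry with planted, level-dependent
# habitat effects.  The generator emulates an episodically gregarious
# population: all animals overwinter and bask communally at a shared
# hibernaculum on a rocky, forested slope, then disperse to individually
# chosen summer core areas whose habitat depends on reproductive class.
# Because the communal zone and the summer cores have opposite covariate
# signatures, the expected sign of several habitat effects differs between
# the individual and population levels -- the ground truth every downstream
# stage is validated against.

#' Simulation configuration
#'
#' Defaults emulate the scale of a 4-year copperhead radio-tracking study:
#' 16 animals contributing 27 animal-seasons, about 32 +/- 7 relocations per
#' season (truncated to 20--49), a class mix of 9 male, 10 nongravid-female
#' and 8 gravid-female seasons, and five spatially autocorrelated
#' percent-cover covariates.
#'
#' @param n_animals number of animals.
#' @param n_seasons total animal-seasons (>= n_animals; extras are assigned to
#'   random animals as repeat seasons).
#' @param class_mix named proportions of seasons over the three reproductive
#'   classes (males are whole animals; female seasons switch between gravid
#'   and nongravid states).
#' @param relocs_mean,relocs_sd,relocs_range per-season relocation count:
#'   normal draw truncated to `relocs_range`.
#' @param phase_schedule fractions of a season spent in the communal spring
#'   phase, dispersal, solitary summer, and communal fall phase; sums to 1.
#' @param sigma_communal,sigma_core isotropic Gaussian spread (m) of
#'   relocations around the hibernaculum and around summer core centers.
#' @param n_summer_cores named list of per-class summer-core count ranges.
#' @param preference_weights class-by-covariate matrix of selection weights on
#'   standardized covariates; summer core centers are drawn with probability
#'   proportional to `exp(w %*% z)`.
#' @param measurement_noise_sd sd (percent) of Gaussian measurement noise
#'   added to covariates sampled at relocations, clipped to [0,100].
#' @param field_range practical range (m) of the exponential-covariance
#'   Gaussian random fields behind each covariate surface.
#' @param extent landscape edge length (m); the grid is square.
#' @param cellsize landscape cell size (m).
#' @param hibernaculum_radius radius (m) of the communal zone (the rocky
#'   forested slope around the hibernaculum).
#' @param n_meadows,meadow_radius number and radius (m) of open meadow
#'   patches.
#' @param zone_offsets logit-scale covariate offsets inside the hibernaculum
#'   zone and the meadows.
#' @param base_logit,logit_sd logit-scale mean and GRF sd of each covariate
#'   before zone offsets; covariates are `100 * plogis(base + sd * z + off)`.
#' @param seed integer root seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(
    n_animals = 16, n_seasons = 27,
    class_mix = c(male = 9, nongravid_female = 10, gravid_female = 8) / 27,
    relocs_mean = 32.3, relocs_sd = 6.9, relocs_range = c(20L, 49L),
    phase_schedule = c(communal_spring = 0.19, dispersal = 0.12,
                       summer = 0.53, communal_fall = 0.16),
    sigma_communal = 20, sigma_core = 10,
    n_summer_cores = list(male = c(1L, 3L), nongravid_female = c(1L, 2L),
                          gravid_female = c(1L, 1L)),
    preference_weights = rbind(
      male             = c(canopy = -2.0, cwd = 0, ground_veg = 2.5, rock = 0, woody_veg = 0),
      nongravid_female = c(canopy = 1.0,  cwd = 0, ground_veg = 0,   rock = 0, woody_veg = 0),
      gravid_female    = c(canopy = 0,    cwd = 2.5, ground_veg = 0, rock = 0, woody_veg = 0)),
    measurement_noise_sd = 5, field_range = 40,
    extent = 600, cellsize = 2, hibernaculum_radius = 120,
    n_meadows = 6, meadow_radius = 45,
    zone_offsets = list(
      hibernaculum = c(canopy = 1.25, cwd = 0, ground_veg = -0.75, rock = 2.0, woody_veg = 0),
      meadow       = c(canopy = -1.25, cwd = 0, ground_veg = 1.5, rock = 0, woody_veg = 0.5)),
    base_logit = c(canopy = 0.85, cwd = -1.1, ground_veg = -0.4,
                   rock = -0.85, woody_veg = -0.6),
    logit_sd = 0.8, seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (abs(sum(phase_schedule) - 1) > 1e-8) stop("phase_schedule must sum to 1")
  if (sigma_communal <= 0 || sigma_core <= 0) stop("sigmas must be > 0")
  if (n_seasons < n_animals) stop("n_seasons must be >= n_animals")
  stopifnot(identical(colnames(preference_weights), HABITAT_COVARIATES),
            identical(sort(rownames(preference_weights)), sort(REPRO_CLASSES)))
  structure(list(
    n_animals = as.integer(n_animals), n_seasons = as.integer(n_seasons),
    class_mix = class_mix, relocs_mean = relocs_mean, relocs_sd = relocs_sd,
    relocs_range = as.integer(relocs_range), phase_schedule = phase_schedule,
    sigma_communal = sigma_communal, sigma_core = sigma_core,
    n_summer_cores = n_summer_cores, preference_weights = preference_weights,
    measurement_noise_sd = measurement_noise_sd, field_range = field_range,
    extent = extent, cellsize = cellsize,
    hibernaculum_radius = hibernaculum_radius,
    n_meadows = as.integer(n_meadows), meadow_radius = meadow_radius,
    zone_offsets = zone_offsets, base_logit = base_logit, logit_sd = logit_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Stationary Gaussian random field with exponential covariance
# exp(-3 d / range) (practical range) by circulant embedding on the doubled
# torus; negative embedding eigenvalues (tiny at these sizes) are clamped.
# The field is standardized to unit empirical variance afterwards, so only
# the correlation structure matters.
grf_exponential <- function(nrows, ncols, cellsize, range) {
  m1 <- 2L * nrows; m2 <- 2L * ncols
  wy <- pmin(0:(m1 - 1L), m1 - 0:(m1 - 1L)) * cellsize
  wx <- pmin(0:(m2 - 1L), m2 - 0:(m2 - 1L)) * cellsize
  D <- sqrt(outer(wy^2, wx^2, "+"))
  lam <- Re(stats::fft(exp(-3 * D / range)))
  lam[lam < 0] <- 0
  eps <- matrix(stats::rnorm(m1 * m2), m1, m2) +
    1i * matrix(stats::rnorm(m1 * m2), m1, m2)
  f <- stats::fft(sqrt(lam) * eps) / sqrt(m1 * m2)
  z <- Re(f)[seq_len(nrows), seq_len(ncols)]
  (z - mean(z)) / stats::sd(z)
}

#' Generate a synthetic covariate landscape
#'
#' Each of the five percent-cover surfaces is a scaled-logistic transform of
#' a standardized Gaussian random field (exponential covariance, practical
#' range `field_range`) plus logit-scale zone offsets: the hibernaculum zone
#' gets elevated rock and canopy and depressed ground vegetation; meadow
#' patches get elevated ground vegetation and depressed canopy.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `landscape`: the grid, five raster matrices
#'   (rows south-first), and the zone geometry.
#' @export
generate_landscape <- function(cfg) {
  nrows <- as.integer(round(cfg$extent / cfg$cellsize))
  ncols <- nrows
  if (nrows < 100 || ncols < 100)
    stop("landscape grid must be at least 100 x 100 cells")
  if (cfg$field_range >= cfg$extent)
    stop("field_range must be smaller than the landscape extent ",
         "(no semivariogram plateau would be observable)")
  grid <- grid_spec(0, 0, cfg$cellsize, nrows, ncols)
  cc <- cell_centers(grid)
  with_seed(child_seed(cfg$seed, "landscape"), {
    hib_center <- c(x = 0.5, y = 0.72) * cfg$extent
    meadows <- list()
    guard <- 0L
    while (length(meadows) < cfg$n_meadows && guard < 10000L) {
      guard <- guard + 1L
      ctr <- stats::runif(2, cfg$meadow_radius, cfg$extent - cfg$meadow_radius)
      if (sqrt(sum((ctr - hib_center)^2)) <
          cfg$hibernaculum_radius + cfg$meadow_radius + 30) next
      ok <- all(vapply(meadows, function(m)
        sqrt(sum((ctr - m$center)^2)) > 2 * cfg$meadow_radius, logical(1)))
      if (ok) meadows[[length(meadows) + 1L]] <-
          list(center = c(x = ctr[1], y = ctr[2]), radius = cfg$meadow_radius)
    }
    dx <- outer(rep(1, nrows), cc$x) - hib_center[["x"]]
    dy <- outer(cc$y, rep(1, ncols)) - hib_center[["y"]]
    in_hib <- (dx^2 + dy^2) <= cfg$hibernaculum_radius^2
    in_meadow <- matrix(FALSE, nrows, ncols)
    for (m in meadows) {
      dx <- outer(rep(1, nrows), cc$x) - m$center[["x"]]
      dy <- outer(cc$y, rep(1, ncols)) - m$center[["y"]]
      in_meadow <- in_meadow | (dx^2 + dy^2) <= m$radius^2
    }
    rasters <- lapply(HABITAT_COVARIATES, function(v) {
      z <- grf_exponential(nrows, ncols, cfg$cellsize, cfg$field_range)
      eta <- cfg$base_logit[[v]] + cfg$logit_sd * z
      eta <- eta + cfg$zone_offsets$hibernaculum[[v]] * in_hib +
        cfg$zone_offsets$meadow[[v]] * in_meadow
      100 * stats::plogis(eta)
    })
    names(rasters) <- HABITAT_COVARIATES
    structure(list(
      grid = grid, rasters = rasters,
      hibernaculum = list(center = hib_center,
                          radius = cfg$hibernaculum_radius),
      meadows = meadows
    ), class = "landscape")
  })
}

# Bilinear interpolation of a south-first raster at arbitrary points,
# clamped to the cell-center envelope at the borders.
bilinear_sample <- function(raster, grid, x, y) {
  cc <- cell_centers(grid)
  fx <- (x - cc$x[1]) / grid$cellsize
  fy <- (y - cc$y[1]) / grid$cellsize
  fx <- pmin(pmax(fx, 0), grid$ncols - 1 - 1e-9)
  fy <- pmin(pmax(fy, 0), grid$nrows - 1 - 1e-9)
  j0 <- floor(fx); i0 <- floor(fy)
  tx <- fx - j0; ty <- fy - i0
  i0 <- i0 + 1L; j0 <- j0 + 1L
  v00 <- raster[cbind(i0, j0)];      v01 <- raster[cbind(i0, j0 + 1L)]
  v10 <- raster[cbind(i0 + 1L, j0)]; v11 <- raster[cbind(i0 + 1L, j0 + 1L)]
  v00 * (1 - tx) * (1 - ty) + v01 * tx * (1 - ty) +
    v10 * (1 - tx) * ty + v11 * tx * ty
}

# truncated-normal relocation count
draw_season_n <- function(cfg) {
  repeat {
    n <- as.integer(round(stats::rnorm(1, cfg$relocs_mean, cfg$relocs_sd)))
    if (n >= cfg$relocs_range[1] && n <= cfg$relocs_range[2]) return(n)
  }
}

# draw points from an isotropic Gaussian truncated to the landscape
rtrunc_gauss <- function(n, center, sigma, extent) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- 2L * (n - nrow(out)) + 4L
    p <- cbind(stats::rnorm(m, center[1], sigma), stats::rnorm(m, center[2], sigma))
    keep <- p[, 1] >= 0 & p[, 1] <= extent & p[, 2] >= 0 & p[, 2] <= extent
    out <- rbind(out, p[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate telemetry over a landscape
#'
#' Each animal-season runs through four phases: communal spring relocations
#' around the hibernaculum, a short dispersal leg, solitary summer
#' relocations around 1--3 class-chosen summer core centers, and a communal
#' fall return. Summer core centers are drawn from landscape cells outside
#' the hibernaculum zone with probability proportional to
#' `exp(w_class . z(covariates))`. Observed covariates are bilinear landscape
#' samples plus Gaussian measurement noise, clipped to [0,100].
#'
#' @param cfg a [sim_config()].
#' @param land the [generate_landscape()] output for the same config.
#' @return a `telemetry` data frame; attributes `complete_flags` (named
#'   logical by season key, all TRUE) and `season_cores` (list of summer core
#'   centers by season key).
#' @export
simulate_telemetry <- function(cfg, land) {
  stopifnot(inherits(land, "landscape"))
  grid <- land$grid
  cc <- cell_centers(grid)
  # standardized covariates per cell, and exclusion of the communal zone
  zmat <- sapply(HABITAT_COVARIATES, function(v) {
    r <- land$rasters[[v]]; (as.vector(r) - mean(r)) / stats::sd(r)
  })
  cx <- rep(cc$x, each = grid$nrows); cy <- rep(cc$y, times = grid$ncols)
  hib <- land$hibernaculum
  outside <- (cx - hib$center[["x"]])^2 + (cy - hib$center[["y"]])^2 >
    hib$radius^2
  with_seed(child_seed(cfg$seed, "telemetry"), {
    n_male_animals <- max(1L, round(cfg$class_mix[["male"]] * cfg$n_animals))
    animal_sex <- c(rep("male", n_male_animals),
                    rep("female", cfg$n_animals - n_male_animals))
    animal_ids <- sprintf("A%02d", seq_len(cfg$n_animals))
    seasons_per_animal <- rep(1L, cfg$n_animals)
    extra <- cfg$n_seasons - cfg$n_animals
    if (extra > 0) {
      add <- sample(rep(seq_len(cfg$n_animals), length.out = 5 * extra), extra)
      for (a in add) seasons_per_animal[a] <- seasons_per_animal[a] + 1L
    }
    p_gravid <- cfg$class_mix[["gravid_female"]] /
      (cfg$class_mix[["gravid_female"]] + cfg$class_mix[["nongravid_female"]])
    rows <- list(); cores_by_season <- list()
    obs_counter <- 0L
    for (a in seq_len(cfg$n_animals)) {
      for (s in seq_len(seasons_per_animal[a])) {
        cls <- if (animal_sex[a] == "male") "male" else
          if (stats::runif(1) < p_gravid) "gravid_female" else "nongravid_female"
        n <- draw_season_n(cfg)
        ph <- cfg$phase_schedule
        n_sp <- max(1L, round(ph[["communal_spring"]] * n))
        n_di <- max(1L, round(ph[["dispersal"]] * n))
        n_fa <- max(1L, round(ph[["communal_fall"]] * n))
        n_su <- n - n_sp - n_di - n_fa
        kr <- cfg$n_summer_cores[[cls]]
        k <- if (kr[1] == kr[2]) kr[1] else sample(seq(kr[1], kr[2]), 1)
        w <- cfg$preference_weights[cls, ]
        logit_pref <- as.vector(zmat %*% w)
        logit_pref <- logit_pref - max(logit_pref[outside])
        prob <- exp(logit_pref) * outside
        if (!any(prob > 0))
          stop("no landscape cell carries positive summer-core preference mass")
        core_cells <- sample.int(length(prob), k, replace = FALSE, prob = prob)
        cores <- cbind(cx[core_cells], cy[core_cells])
        hibc <- c(hib$center[["x"]], hib$center[["y"]])
        p_sp <- rtrunc_gauss(n_sp, hibc, cfg$sigma_communal, cfg$extent)
        tt <- seq_len(n_di) / (n_di + 1)
        p_di <- cbind((1 - tt) * hibc[1] + tt * cores[1, 1],
                      (1 - tt) * hibc[2] + tt * cores[1, 2]) +
          matrix(stats::rnorm(2 * n_di, 0, 1.5 * cfg$sigma_core), n_di, 2)
        p_di[, 1] <- pmin(pmax(p_di[, 1], 0), cfg$extent)
        p_di[, 2] <- pmin(pmax(p_di[, 2], 0), cfg$extent)
        core_of <- sort(rep_len(seq_len(k), n_su))
        p_su <- do.call(rbind, lapply(seq_len(k), function(ci)
          rtrunc_gauss(sum(core_of == ci), cores[ci, ], cfg$sigma_core,
                       cfg$extent)))
        p_fa <- rtrunc_gauss(n_fa, hibc, cfg$sigma_communal, cfg$extent)
        pts <- rbind(p_sp, p_di, p_su, p_fa)
        phase <- rep(c("communal_spring", "dispersal", "summer",
                       "communal_fall"), c(n_sp, n_di, n_su, n_fa))
        cov <- sapply(HABITAT_COVARIATES, function(v)
          pmin(pmax(bilinear_sample(land$rasters[[v]], grid,
                                    pts[, 1], pts[, 2]) +
                      stats::rnorm(n, 0, cfg$measurement_noise_sd), 0), 100))
        day0 <- as.Date(sprintf("%d-04-15", 2015 + s))
        df <- data.frame(
          obs_id = obs_counter + seq_len(n),
          animal_id = animal_ids[a], season_id = sprintf("s%d", s),
          class = cls,
          timestamp = as.character(day0 + round(seq(0, 165, length.out = n))),
          x = pts[, 1], y = pts[, 2], stringsAsFactors = FALSE)
        df[HABITAT_COVARIATES] <- cov
        df$phase <- phase
        obs_counter <- obs_counter + n
        key <- season_key(animal_ids[a], sprintf("s%d", s))
        cores_by_season[[key]] <- cores
        rows[[length(rows) + 1L]] <- df
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    flags <- rep(TRUE, length(cores_by_season))
    names(flags) <- names(cores_by_season)
    structure(out, complete_flags = flags, season_cores = cores_by_season,
              class = c("telemetry", "data.frame"))
  })
}

#' Record the planted ground truth of a simulation
#'
#' Summarizes the covariate structure the generator planted: the expected
#' sign of each covariate's effect on core-area membership at the individual
#' level (driven by the class-weighted summer-core preferences) and at the
#' population level (driven by the hibernaculum-zone covariate offsets), and
#' the expected per-covariate class contrasts relative to gravid females.
#'
#' @param cfg a [sim_config()].
#' @param land the matching [generate_landscape()] output.
#' @return an object of class `truth_record` with elements `ind_sign`,
#'   `pop_sign` (named vectors in -1/0/+1), `class_contrast_sign` (class x
#'   covariate matrix of signs vs the gravid-female reference), and the zone
#'   covariate contrasts actually realized on the landscape.
#' @export
planted_truth <- function(cfg, land) {
  stopifnot(inherits(land, "landscape"))
  sgn <- function(v) ifelse(abs(v) < 1e-8, 0, sign(v))
  mix <- cfg$class_mix[rownames(cfg$preference_weights)]
  ind_raw <- as.vector(mix %*% cfg$preference_weights)
  names(ind_raw) <- HABITAT_COVARIATES
  pop_raw <- cfg$zone_offsets$hibernaculum[HABITAT_COVARIATES]
  contrast <- sweep(cfg$preference_weights, 2,
                    cfg$preference_weights["gravid_female", ])
  # realized zone contrast: hibernaculum-zone mean minus landscape mean
  grid <- land$grid; cc <- cell_centers(grid)
  dx <- outer(rep(1, grid$nrows), cc$x) - land$hibernaculum$center[["x"]]
  dy <- outer(cc$y, rep(1, grid$ncols)) - land$hibernaculum$center[["y"]]
  in_hib <- (dx^2 + dy^2) <= land$hibernaculum$radius^2
  zone_contrast <- vapply(HABITAT_COVARIATES, function(v)
    mean(land$rasters[[v]][in_hib]) - mean(land$rasters[[v]]), numeric(1))
  structure(list(
    ind_sign = sgn(ind_raw), pop_sign = sgn(pop_raw),
    class_contrast_sign = sgn(contrast),
    zone_contrast = zone_contrast,
    preference_weights = cfg$preference_weights
  ), class = "truth_record")
}
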