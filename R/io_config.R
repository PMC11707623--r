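# Run configuration, grid geometry, seeded RNG streams, and file formats
# (telemetry CSV, ESRI ASCII grids, GeoJSON regions).

#' Habitat covariate names
#'
#' The five structural habitat covariates measured at each relocation, all on
#' a percent-cover scale (0--100): canopy closure, coarse woody debris,
#' ground-layer vegetation, exposed surface rock, and woody understory
#' vegetation.
#' @export
HABITAT_COVARIATES <- c("canopy", "cwd", "ground_veg", "rock", "woody_veg")

#' Reproductive class levels
#'
#' The three reproductive classes used throughout: males, nongravid females,
#' and gravid females.
#' @export
REPRO_CLASSES <- c("male", "nongravid_female", "gravid_female")

#' Analysis run configuration
#'
#' Bundles every tunable constant of the analysis pipeline. Defaults follow
#' the conventions of the multilevel core-area workflow: 95% MCP home ranges,
#' 30% volume-contour core areas, bandwidth tuned in 1-m increments, a
#' 1000-iteration population resampling average, and a 20-observation season
#' filter.
#'
#' @param mcp_percent fraction of relocations retained by the percent MCP.
#' @param core_isopleth UD volume fraction defining core areas.
#' @param outer_isopleth UD volume fraction matched to the MCP area during
#'   bandwidth tuning.
#' @param bandwidth_step bandwidth increment in meters.
#' @param pop_ud_iterations number of one-season-per-animal resampling
#'   iterations for the population UD.
#' @param min_obs_per_season minimum relocations for a season to be retained.
#' @param grid_cell raster cell size in meters.
#' @param grid_margin margin in meters added around point extents when
#'   building grids.
#' @param delta_aic_cut ΔAIC cutoff delimiting the model-averaging set.
#' @param vif_max variance-inflation-factor threshold flagged by [vif()].
#' @param bootstrap_iterations bootstrap resamples for summary statistics.
#' @param h_max bandwidth cap (m) beyond which tuning aborts with an error.
#' @param seed integer root seed; all stochastic stages derive child streams
#'   from it via [child_seed()].
#' @return an object of class `run_config` (a validated list).
#' @export
run_config <- function(mcp_percent = 0.95, core_isopleth = 0.30,
                       outer_isopleth = 0.95, bandwidth_step = 1.0,
                       pop_ud_iterations = 1000, min_obs_per_season = 20,
                       grid_cell = 2.0, grid_margin = 50.0,
                       delta_aic_cut = 2.0, vif_max = 2.0,
                       bootstrap_iterations = 1000, h_max = 500,
                       seed = 1L) {
  fr <- c(mcp_percent = mcp_percent, core_isopleth = core_isopleth,
          outer_isopleth = outer_isopleth)
  if (any(fr <= 0 | fr >= 1))
    stop("mcp_percent, core_isopleth and outer_isopleth must lie in (0,1)")
  if (core_isopleth >= outer_isopleth)
    stop("core_isopleth must be smaller than outer_isopleth")
  cnt <- c(pop_ud_iterations = pop_ud_iterations,
           min_obs_per_season = min_obs_per_season,
           bootstrap_iterations = bootstrap_iterations)
  if (any(cnt < 1)) stop("iteration and observation counts must be >= 1")
  if (bandwidth_step <= 0) stop("bandwidth_step must be > 0")
  if (grid_cell <= 0 || grid_margin < 0) stop("invalid grid geometry")
  structure(list(
    mcp_percent = mcp_percent, core_isopleth = core_isopleth,
    outer_isopleth = outer_isopleth, bandwidth_step = bandwidth_step,
    pop_ud_iterations = as.integer(pop_ud_iterations),
    min_obs_per_season = as.integer(min_obs_per_season),
    grid_cell = grid_cell, grid_margin = grid_margin,
    delta_aic_cut = delta_aic_cut, vif_max = vif_max,
    bootstrap_iterations = as.integer(bootstrap_iterations),
    h_max = h_max, seed = as.integer(seed)
  ), class = "run_config")
}

# ---- seeded streams ---------------------------------------------------------

#' Derive a child seed for a named pipeline stage
#'
#' Each stochastic stage draws from its own stream keyed by stage name, so
#' changing the amount of randomness consumed by one stage never perturbs
#' another. The child seed is a deterministic hash of the root seed and the
#' stage label, kept below 2^31.
#'
#' @param seed integer root seed.
#' @param stage character stage label.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's RNG
#' state, so seeded helpers never disturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# ---- grid geometry ----------------------------------------------------------

#' Define a raster grid
#'
#' Grids use a lower-left origin: row 1 is the southernmost row, and the
#' center of cell (i, j) is at (xll + (j - 0.5) * cellsize,
#' yll + (i - 0.5) * cellsize).
#'
#' @param xll,yll coordinates (m) of the grid's lower-left corner.
#' @param cellsize cell edge length in meters.
#' @param nrows,ncols grid dimensions.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(xll, yll, cellsize, nrows, ncols) {
  stopifnot(cellsize > 0, nrows >= 1, ncols >= 1)
  structure(list(xll = xll, yll = yll, cellsize = cellsize,
                 nrows = as.integer(nrows), ncols = as.integer(ncols)),
            class = "grid_spec")
}

#' Build a grid covering a point set with a margin
#'
#' @param x,y point coordinates (m).
#' @param cellsize cell edge length (m).
#' @param margin margin (m) added on every side.
#' @return a [grid_spec()].
#' @export
grid_for_points <- function(x, y, cellsize, margin) {
  xll <- min(x) - margin; yll <- min(y) - margin
  ncols <- max(1L, ceiling((max(x) + margin - xll) / cellsize))
  nrows <- max(1L, ceiling((max(y) + margin - yll) / cellsize))
  grid_spec(xll, yll, cellsize, nrows, ncols)
}

#' Map points to grid cells
#'
#' Cell lookup is by `floor((coord - origin)/cellsize)`; points on the exact
#' right or top edge of the grid are assigned to the last column or row.
#'
#' @param grid a [grid_spec()].
#' @param x,y coordinates.
#' @return a list with integer vectors `row`, `col` (1-based) and `index`
#'   (row-major, 1-based); `NA` where a point falls outside the grid.
#' @export
point_to_cell <- function(grid, x, y) {
  cj <- floor((x - grid$xll) / grid$cellsize) + 1L
  ri <- floor((y - grid$yll) / grid$cellsize) + 1L
  xmax <- grid$xll + grid$ncols * grid$cellsize
  ymax <- grid$yll + grid$nrows * grid$cellsize
  cj[x == xmax] <- grid$ncols
  ri[y == ymax] <- grid$nrows
  bad <- cj < 1L | cj > grid$ncols | ri < 1L | ri > grid$nrows
  cj[bad] <- NA_integer_; ri[bad] <- NA_integer_
  list(row = ri, col = cj, index = (ri - 1L) * grid$ncols + cj)
}

#' Cell-center coordinate vectors of a grid
#' @param grid a [grid_spec()].
#' @return list with vectors `x` (length ncols) and `y` (length nrows).
#' @export
cell_centers <- function(grid) {
  list(x = grid$xll + (seq_len(grid$ncols) - 0.5) * grid$cellsize,
       y = grid$yll + (seq_len(grid$nrows) - 0.5) * grid$cellsize)
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    a$nrows == b$nrows && a$ncols == b$ncols
}

# ---- telemetry CSV ----------------------------------------------------------

TELEMETRY_COLUMNS <- c("obs_id", "animal_id", "season_id", "class",
                       "timestamp", "x", "y", HABITAT_COVARIATES)

#' Combined animal-season key
#'
#' Season ids are unique only within an animal; this key identifies a season
#' globally and is used as the grouping unit throughout.
#' @param animal_id,season_id identifier vectors.
#' @return character vector of keys.
#' @export
season_key <- function(animal_id, season_id) paste(animal_id, season_id, sep = "|")

validate_telemetry <- function(df) {
  missing_cols <- setdiff(TELEMETRY_COLUMNS, names(df))
  if (length(missing_cols))
    stop("telemetry is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  bad_class <- !df$class %in% REPRO_CLASSES
  if (any(bad_class))
    stop("invalid reproductive class value(s): ",
         paste(unique(df$class[bad_class]), collapse = ", "),
         " (rows ", paste(utils::head(which(bad_class), 5), collapse = ", "), ")")
  cov <- as.matrix(df[HABITAT_COVARIATES])
  out_of_range <- which(rowSums(cov < 0 | cov > 100, na.rm = TRUE) > 0)
  if (length(out_of_range))
    stop("covariate values outside [0,100] in row(s): ",
         paste(utils::head(out_of_range, 10), collapse = ", "))
  # reject coordinates that look like unprojected lat/lon: tiny extent inside
  # the geographic envelope.  analysis requires planar meters.
  if (all(abs(df$x) <= 180) && all(abs(df$y) <= 90) &&
      diff(range(df$x)) < 5 && diff(range(df$y)) < 5)
    stop("coordinates look geographic (degrees); supply projected planar meters")
  invisible(df)
}

#' Read a telemetry CSV
#'
#' Expects one row per relocation with animal id, season id, reproductive
#' class, timestamp, planar x/y in meters, and the five percent-cover habitat
#' covariates. Rows with missing coordinates or covariates are dropped and
#' reported in the `rejected` attribute.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping required column names
#'   to the names used in the file, e.g. `c(x = "easting")`.
#' @return a `telemetry` data frame (one row per retained observation) with a
#'   `rejected` attribute describing dropped rows.
#' @export
read_telemetry <- function(path, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (std in names(schema)) {
      if (!schema[[std]] %in% names(df))
        stop("schema maps '", std, "' to absent column '", schema[[std]], "'")
      names(df)[names(df) == schema[[std]]] <- std
    }
  }
  missing_cols <- setdiff(TELEMETRY_COLUMNS, names(df))
  if (length(missing_cols))
    stop("telemetry CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[TELEMETRY_COLUMNS]
  num_cols <- c("x", "y", HABITAT_COVARIATES)
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])
  incomplete <- !stats::complete.cases(df[num_cols]) |
    !is.finite(df$x) | !is.finite(df$y)
  rejected <- df[incomplete, , drop = FALSE]
  df <- df[!incomplete, , drop = FALSE]
  if (!nrow(df)) stop("no complete telemetry rows in ", path)
  validate_telemetry(df)
  rownames(df) <- NULL
  structure(df, rejected = rejected, class = c("telemetry", "data.frame"))
}

#' Write a telemetry CSV
#' @param data a telemetry data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_telemetry <- function(data, path) {
  utils::write.csv(as.data.frame(data)[TELEMETRY_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- ESRI ASCII grids -------------------------------------------------------

#' Write a utilization distribution as an ESRI ASCII grid
#'
#' Stores per-square-meter density with the standard six-line header
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value). `NaN` cells are
#' written as NODATA. Values round-trip through [read_raster()] to 1e-10.
#'
#' @param ud a normalized `ud_raster` (see [kde_ud()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(ud, path) {
  stopifnot(inherits(ud, "ud_raster"))
  g <- ud$grid
  mass <- sum(ud$density[is.finite(ud$density)]) * g$cellsize^2
  if (abs(mass - 1) > 1e-6)
    stop("refusing to write unnormalized UD (total mass ", format(mass), ")")
  nodata <- -9999
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("ncols", g$ncols), paste("nrows", g$nrows),
    paste("xllcorner", format(g$xll, digits = 17)),
    paste("yllcorner", format(g$yll, digits = 17)),
    paste("cellsize", format(g$cellsize, digits = 17)),
    paste("NODATA_value", nodata)
  ), con)
  # ASCII grids list rows north to south; our row 1 is the southernmost
  for (i in rev(seq_len(g$nrows))) {
    row <- ud$density[i, ]
    row_chr <- ifelse(is.nan(row), as.character(nodata),
                      formatC(row, format = "e", digits = 17))
    writeLines(paste(row_chr, collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_raster()]
#' @param path file path.
#' @return a `ud_raster` (bandwidth `NA`; NODATA cells become `NaN`).
#' @export
read_raster <- function(path) {
  hdr <- utils::read.table(path, nrows = 6, col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  vals <- stats::setNames(hdr$value, tolower(hdr$key))
  g <- grid_spec(vals[["xllcorner"]], vals[["yllcorner"]], vals[["cellsize"]],
                 vals[["nrows"]], vals[["ncols"]])
  body <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = g$nrows, ncol = g$ncols, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NaN
  m <- m[rev(seq_len(g$nrows)), , drop = FALSE]  # back to south-first rows
  structure(list(grid = g, density = m, bandwidth = NA_real_,
                 source = list(level = NA_character_, ids = character())),
            class = "ud_raster")
}

# ---- GeoJSON regions --------------------------------------------------------

# Outline the union of grid-cell squares by edge cancellation: each member
# cell contributes its four counter-clockwise edges; edges shared by two
# member cells cancel, and the survivors chain into rings (CCW = outer
# boundary, CW = hole).  At corner-touch vertices the sharpest-right turn is
# taken so diagonal neighbours stay separate polygons.
cellset_rings <- function(cells, grid) {
  idx <- sort(unique(as.integer(cells)))
  if (!length(idx)) stop("empty cell set")
  ri <- (idx - 1L) %/% grid$ncols
  cj <- (idx - 1L) %% grid$ncols
  d <- grid$cellsize
  x0 <- grid$xll + cj * d; y0 <- grid$yll + ri * d
  # vertices keyed on the integer lattice to avoid float comparison
  vkey <- function(ix, iy) paste(ix, iy)
  from <- c(cj,     cj + 1L, cj + 1L, cj)
  fromy <- c(ri,    ri,      ri + 1L, ri + 1L)
  to <- c(cj + 1L,  cj + 1L, cj,      cj)
  toy <- c(ri,      ri + 1L, ri + 1L, ri)
  edges <- data.frame(fx = from, fy = fromy, tx = to, ty = toy)
  ek <- paste(pmin(edges$fx, edges$tx), pmin(edges$fy, edges$ty),
              pmax(edges$fx, edges$tx), pmax(edges$fy, edges$ty))
  keep <- !(ek %in% ek[duplicated(ek)])
  edges <- edges[keep, , drop = FALSE]
  # index surviving edges by start vertex
  starts <- split(seq_len(nrow(edges)), vkey(edges$fx, edges$fy))
  used <- logical(nrow(edges))
  rings <- list()
  for (e0 in seq_len(nrow(edges))) {
    if (used[e0]) next
    ring <- e0; used[e0] <- TRUE
    cur <- e0
    repeat {
      nx <- edges$tx[cur]; ny <- edges$ty[cur]
      cand <- starts[[vkey(nx, ny)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # sharpest left turn keeps the interior on the left through
        # corner-touch vertices, so diagonal neighbours stay separate
        din <- c(edges$tx[cur] - edges$fx[cur], edges$ty[cur] - edges$fy[cur])
        turn <- vapply(cand, function(e) {
          dout <- c(edges$tx[e] - edges$fx[e], edges$ty[e] - edges$fy[e])
          atan2(din[1] * dout[2] - din[2] * dout[1],
                din[1] * dout[1] + din[2] * dout[2])
        }, numeric(1))
        cand <- cand[which.max(turn)]
      }
      cur <- cand[1L]; used[cur] <- TRUE; ring <- c(ring, cur)
      if (edges$tx[cur] == edges$fx[ring[1]] &&
          edges$ty[cur] == edges$fy[ring[1]]) break
    }
    xs <- grid$xll + c(edges$fx[ring], edges$fx[ring[1]]) * d
    ys <- grid$yll + c(edges$fy[ring], edges$fy[ring[1]]) * d
    rings[[length(rings) + 1L]] <- cbind(x = xs, y = ys)
  }
  rings
}

ring_signed_area <- function(r) {
  n <- nrow(r)
  sum(r[-n, 1] * r[-1, 2] - r[-1, 1] * r[-n, 2]) / 2
}

point_in_ring <- function(px, py, r) {
  n <- nrow(r) - 1L; inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((r[i, 2] > py) != (r[j, 2] > py) &&
        px < (r[j, 1] - r[i, 1]) * (py - r[i, 2]) / (r[j, 2] - r[i, 2]) + r[i, 1])
      inside <- !inside
    j <- i
  }
  inside
}

#' Write a cell set as a GeoJSON MultiPolygon
#'
#' The union of the member cells' squares is polygonized (outer rings CCW,
#' holes CW, nested per the GeoJSON spec) in the dataset's planar coordinate
#' units.
#'
#' @param cells a `cell_set` (see [volume_contour()]) or an integer vector of
#'   row-major cell indices when `grid` is given.
#' @param path output file.
#' @param grid grid to use when `cells` is a bare index vector.
#' @return `path`, invisibly.
#' @export
write_region <- function(cells, path, grid = NULL) {
  if (inherits(cells, "cell_set")) {
    grid <- cells$grid; members <- cells$cells
  } else members <- cells
  if (is.null(grid)) stop("grid must be supplied with a bare cell index vector")
  if (!length(members)) stop("empty cell set")
  rings <- cellset_rings(members, grid)
  areas <- vapply(rings, ring_signed_area, numeric(1))
  outer <- which(areas > 0); holes <- which(areas < 0)
  polys <- lapply(outer, function(o) list(rings[[o]]))
  if (length(holes)) {
    for (h in holes) {
      px <- rings[[h]][1, 1]; py <- rings[[h]][1, 2]
      owner <- which(vapply(outer, function(o)
        point_in_ring(px, py, rings[[o]]), logical(1)))[1]
      polys[[owner]] <- c(polys[[owner]], list(rings[[h]]))
    }
  }
  coords <- lapply(polys, function(p)
    lapply(p, function(r) lapply(seq_len(nrow(r)),
                                 function(i) c(r[i, 1], r[i, 2]))))
  gj <- list(type = "Feature",
             geometry = list(type = "MultiPolygon", coordinates = coords),
             properties = list(n_cells = length(unique(members)),
                               cell_area_m2 = grid$cellsize^2))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON MultiPolygon written by [write_region()]
#' @param path file path.
#' @return list of polygons; each polygon is a list of ring matrices.
#' @export
read_region <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$geometry$coordinates, function(poly)
    lapply(poly, function(ring)
      do.call(rbind, lapply(ring, function(pt)
        c(x = pt[[1]], y = pt[[2]])))))
}
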