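# Percent minimum convex polygon home ranges and the sample-size
# stabilization analysis.

# shoelace area of an (unclosed) convex ring
polygon_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2])) / 2
}

#' Percent minimum convex polygon
#'
#' Retains the `floor(percent * n)` points nearest the arithmetic centroid of
#' all points (Euclidean distance, ties at the retention boundary broken by
#' observation id) and returns their convex hull. `percent = 1` retains all
#' points.
#'
#' @param points data frame with columns `x`, `y` and optionally `obs_id`
#'   (used for deterministic tie-breaking; defaults to row order).
#' @param percent fraction of points to retain, in (0, 1].
#' @return an object of class `mcp_polygon` with the ordered hull ring
#'   (`vertices`), ids of retained points (`retained_obs`), and `area` in
#'   square meters.
#' @export
mcp <- function(points, percent = 0.95) {
  if (percent <= 0 || percent > 1) stop("percent must be in (0, 1]")
  n <- nrow(points)
  if (is.null(n) || n < 5) stop("mcp requires at least 5 points")
  ids <- if ("obs_id" %in% names(points)) points$obs_id else seq_len(n)
  ctr <- c(mean(points$x), mean(points$y))
  d <- sqrt((points$x - ctr[1])^2 + (points$y - ctr[2])^2)
  keep_n <- floor(percent * n)
  ord <- order(d, ids)
  keep <- ord[seq_len(keep_n)]
  px <- points$x[keep]; py <- points$y[keep]
  uniq <- !duplicated(cbind(px, py))
  hull_idx <- grDevices::chull(px[uniq], py[uniq])
  ring <- cbind(x = px[uniq][hull_idx], y = py[uniq][hull_idx])
  if (nrow(ring) < 3 || polygon_area(ring) <= 0)
    stop("retained points are collinear; MCP is degenerate")
  structure(list(percent = percent, vertices = ring,
                 retained_obs = ids[keep], area = polygon_area(ring)),
            class = "mcp_polygon")
}

#' Filter animal-seasons by sample size and completeness
#'
#' Removes seasons with fewer than `min_obs` relocations and seasons flagged
#' incomplete (e.g. truncated by mortality or transmitter failure);
#' completeness is external metadata and cannot be inferred from coordinates.
#' The boundary is inclusive: a season with exactly `min_obs` relocations is
#' retained.
#'
#' @param data a telemetry data frame.
#' @param min_obs minimum relocations per season.
#' @param complete_flags named logical vector by [season_key()]; seasons
#'   absent from it are assumed complete. Defaults to the data's own
#'   `complete_flags` attribute.
#' @return the filtered telemetry; attribute `removed` is a data frame of
#'   removed seasons with reasons.
#' @export
filter_seasons <- function(data, min_obs = 20, complete_flags = NULL) {
  if (is.null(complete_flags)) complete_flags <- attr(data, "complete_flags")
  key <- season_key(data$animal_id, data$season_id)
  counts <- table(key)
  complete <- rep(TRUE, length(counts)); names(complete) <- names(counts)
  if (!is.null(complete_flags)) {
    known <- intersect(names(complete_flags), names(complete))
    complete[known] <- complete_flags[known]
  }
  too_few <- counts < min_obs
  drop <- too_few | !complete
  removed <- data.frame(
    season = names(counts)[drop],
    n = as.integer(counts[drop]),
    reason = ifelse(too_few[drop] & !complete[drop], "too few; incomplete",
                    ifelse(too_few[drop], "fewer than min_obs", "incomplete")),
    stringsAsFactors = FALSE)
  out <- data[!key %in% removed$season, , drop = FALSE]
  if (!nrow(out)) warning("no seasons retained after filtering")
  attrs <- attributes(data)
  out <- structure(out, class = c("telemetry", "data.frame"),
                   removed = removed)
  if (!is.null(attrs$complete_flags))
    attr(out, "complete_flags") <-
      attrs$complete_flags[!names(attrs$complete_flags) %in% removed$season]
  if (!is.null(attrs$season_cores))
    attr(out, "season_cores") <-
      attrs$season_cores[!names(attrs$season_cores) %in% removed$season]
  out
}

#' MCP area as a function of sample size
#'
#' For each requested size, repeatedly draws a season uniformly among seasons
#' with at least that many relocations, subsamples that many observations
#' without replacement, and records the 95% (or `percent`) MCP area; the mean
#' over iterations traces how home-range estimates stabilize with sample
#' size.
#'
#' @param data a telemetry data frame.
#' @param sizes integer sample sizes (each >= 5).
#' @param n_iter iterations per size.
#' @param percent MCP percent.
#' @param seed integer seed.
#' @return an `area_curve` data frame with columns `size`, `mean_area`,
#'   `n_iterations`.
#' @export
mcp_area_curve <- function(data, sizes, n_iter = 100, percent = 0.95,
                           seed = 1L) {
  key <- season_key(data$animal_id, data$season_id)
  counts <- table(key)
  if (any(sizes < 5)) stop("sizes must be >= 5")
  bad <- sizes[sizes > max(counts)]
  if (length(bad))
    stop("no season has enough observations for size(s): ",
         paste(bad, collapse = ", "))
  with_seed(seed, {
    mean_area <- vapply(sizes, function(sz) {
      eligible <- names(counts)[counts >= sz]
      mean(vapply(seq_len(n_iter), function(i) {
        sk <- if (length(eligible) == 1) eligible else sample(eligible, 1)
        rows <- which(key == sk)
        sub <- data[sample(rows, sz), , drop = FALSE]
        mcp(sub, percent)$area
      }, numeric(1)))
    }, numeric(1))
    structure(data.frame(size = sizes, mean_area = mean_area,
                         n_iterations = n_iter),
              class = c("area_curve", "data.frame"))
  })
}
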