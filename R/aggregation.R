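#' Geometric mean assimilating zeros
#'
#' Abundance data such as standardised krill net catches are right-skewed and
#' zero-inflated, so cells are summarised by a geometric rather than
#' arithmetic mean. Plain geometric means are undefined when any observation
#' is zero; this estimator assimilates zeros by weighting the geometric mean
#' of the positive observations by the positive fraction:
#'
#' \deqn{G = \frac{n_{pos}}{n} \exp\left(\frac{1}{n_{pos}}\sum_{x_i>0}\log x_i\right)}
#'
#' With no zeros it reduces to the ordinary geometric mean; with all zeros it
#' is 0; otherwise it is at most the geometric mean of the positive subset.
#'
#' @param values Numeric vector of nonnegative observations (at least one).
#' @return A single nonnegative number.
#' @examples
#' geometric_mean_with_zeros(c(4, 9))        # 6
#' geometric_mean_with_zeros(c(0, exp(2)))   # exp(2) / 2
#' @export
geometric_mean_with_zeros <- function(values) {
  if (length(values) == 0) {
    stop("`values` must contain at least one observation", call. = FALSE)
  }
  if (anyNA(values)) stop("`values` must not contain NA", call. = FALSE)
  if (any(values < 0)) {
    stop("`values` must be nonnegative; got ", min(values), call. = FALSE)
  }
  pos <- values[values > 0]
  if (length(pos) == 0) return(0)
  (length(pos) / length(values)) * exp(mean(log(pos)))
}

#' Grid point samples by zero-assimilating geometric mean
#'
#' Pools point samples (e.g. standardised krill densities) into grid cells:
#' samples are month-filtered (default January-March, the months the krill
#' data represent), assigned to cells, and each cell summarised with
#' [geometric_mean_with_zeros()]. Samples are pooled across all years within a
#' cell, so the result is an interannual mean. Cells with no samples are
#' missing, leaving the layer patchy where sampling was lacking.
#'
#' @param samples Data frame with columns `lon`, `lat`, `date` (a `Date` or
#'   parseable string), and nonnegative `value`.
#' @param grid A `grid_spec`.
#' @param month_filter Integer months to retain (1 = January); `NULL` keeps
#'   all.
#' @return A `value_layer` with per-cell geometric means and `n_obs` counts.
#' @export
grid_point_samples <- function(samples, grid, month_filter = 1:3) {
  stopifnot(is.data.frame(samples),
            all(c("lon", "lat", "date", "value") %in% names(samples)))
  if (any(samples$value < 0, na.rm = TRUE)) {
    stop("sample values must be nonnegative", call. = FALSE)
  }
  dates <- as.Date(samples$date)
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(month_filter)) {
    keep <- as.integer(format(dates, "%m")) %in% month_filter
  }
  out <- value_layer(grid, NA_real_,
                     n_obs = matrix(0L, grid$n_rows, grid$n_cols))
  sub <- samples[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no samples left after month filtering; layer is fully missing",
            call. = FALSE)
    return(out)
  }
  idx <- assign_cell(sub$lon, sub$lat, grid)
  ok <- !is.na(idx$col)
  sub <- sub[ok, , drop = FALSE]
  idx <- idx[ok, , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no samples fall inside the grid; layer is fully missing",
            call. = FALSE)
    return(out)
  }
  key <- idx$row * grid$n_cols + idx$col
  agg <- tapply(sub$value, key, geometric_mean_with_zeros)
  cnt <- tapply(sub$value, key, length)
  kcol <- as.integer(names(agg)) %% grid$n_cols
  krow <- as.integer(names(agg)) %/% grid$n_cols
  mi <- cell_mat_index(kcol, krow, grid)
  out$values[mi] <- as.numeric(agg)
  out$n_obs[mi] <- as.integer(cnt)
  out
}

#' Regrid a fine raster by zero-assimilating geometric mean
#'
#' Aggregates a fine-resolution field (e.g. 1/12 degree chlorophyll-a) onto
#' the analysis grid: each coarse cell takes the geometric mean (zeros
#' assimilated) of the fine-cell values whose centres fall inside it. Missing
#' fine cells are excluded before averaging.
#'
#' @param raster A [fine_raster()] with nonnegative values (or `NA`).
#' @param grid A `grid_spec`; must be strictly coarser than the raster.
#' @return A `value_layer`; `n_obs` counts contributing fine cells.
#' @export
regrid_raster_geomean <- function(raster, grid) {
  stopifnot(inherits(raster, "fine_raster"), is_grid_spec(grid))
  res_lon <- if (length(raster$lon) > 1) min(diff(raster$lon)) else Inf
  res_lat <- if (length(raster$lat) > 1) min(diff(raster$lat)) else Inf
  if (res_lon >= grid$lon_width || res_lat >= grid$lat_width) {
    stop("fine raster resolution (", signif(res_lon, 4), " x ",
         signif(res_lat, 4), " deg) must be finer than the target grid (",
         grid$lon_width, " x ", grid$lat_width, " deg)", call. = FALSE)
  }
  pts <- expand.grid(lon = raster$lon, lat = raster$lat)
  vals <- as.vector(t(raster$values)) # row (lat) slow, lon fast -> matches expand.grid
  ok <- !is.na(vals) & pts$lon >= -180 & pts$lon <= 180
  pts <- pts[ok, , drop = FALSE]
  vals <- vals[ok]
  out <- value_layer(grid, NA_real_,
                     n_obs = matrix(0L, grid$n_rows, grid$n_cols))
  if (length(vals) == 0) return(out)
  idx <- assign_cell(pts$lon, pts$lat, grid)
  inside <- !is.na(idx$col)
  idx <- idx[inside, , drop = FALSE]
  vals <- vals[inside]
  if (length(vals) == 0) return(out)
  key <- idx$row * grid$n_cols + idx$col
  agg <- tapply(vals, key, geometric_mean_with_zeros)
  cnt <- tapply(vals, key, length)
  kcol <- as.integer(names(agg)) %% grid$n_cols
  krow <- as.integer(names(agg)) %/% grid$n_cols
  mi <- cell_mat_index(kcol, krow, grid)
  out$values[mi] <- as.numeric(agg)
  out$n_obs[mi] <- as.integer(cnt)
  out
}
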