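#' Define the common circumpolar analysis grid
#'
#' All layers in the pipeline are projected onto one longitude-latitude grid.
#' The default reproduces the 9 degree longitude x 3 degree latitude grid
#' south of 45 degrees S on which krill net samples were pooled; the krill
#' cell size sets the spatial resolution of every map downstream.
#'
#' Columns are numbered 0-based from -180 degrees eastward, rows 0-based from
#' the southern limit northward. Cell intervals are half-open `[lo, hi)` on
#' both axes, so every in-range coordinate belongs to exactly one cell, and
#' longitude +180 wraps to the column of -180.
#'
#' @param lon_width Cell width in degrees longitude; 360 must be an integer
#'   multiple of it.
#' @param lat_width Cell height in degrees latitude; the latitude span must be
#'   an integer multiple of it.
#' @param lat_north_limit Northern edge of the grid, degrees (negative = south).
#' @param lat_south_limit Southern edge of the grid, degrees.
#' @param earth_radius_km Radius of the authalic sphere used for areas and
#'   distances, km.
#' @return An object of class `grid_spec`: a list with the widths, limits,
#'   `n_cols`, `n_rows`, and `earth_radius_km`.
#' @examples
#' g <- build_grid()
#' g$n_cols # 40
#' g$n_rows # 15
#' @export
build_grid <- function(lon_width = 9, lat_width = 3,
                       lat_north_limit = -45, lat_south_limit = -90,
                       earth_radius_km = 6371.0072) {
  stopifnot(is.numeric(lon_width), is.numeric(lat_width),
            lon_width > 0, lat_width > 0,
            lat_north_limit > lat_south_limit,
            lat_south_limit >= -90, lat_north_limit <= 90)
  n_cols <- 360 / lon_width
  if (abs(n_cols - round(n_cols)) > 1e-9) {
    stop("`lon_width` (", lon_width, ") must divide 360 evenly", call. = FALSE)
  }
  span <- lat_north_limit - lat_south_limit
  n_rows <- span / lat_width
  if (abs(n_rows - round(n_rows)) > 1e-9) {
    stop("`lat_width` (", lat_width, ") must divide the latitude span (",
         span, ") evenly", call. = FALSE)
  }
  structure(
    list(lon_width = lon_width, lat_width = lat_width,
         lat_north_limit = lat_north_limit, lat_south_limit = lat_south_limit,
         n_cols = as.integer(round(n_cols)), n_rows = as.integer(round(n_rows)),
         earth_radius_km = earth_radius_km),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g deg lon x %g deg lat, %d cols x %d rows, lat [%g, %g)\n",
              x$lon_width, x$lat_width, x$n_cols, x$n_rows,
              x$lat_south_limit, x$lat_north_limit))
  invisible(x)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Assign coordinates to grid cells
#'
#' Vectorised point-in-cell lookup with half-open `[lo, hi)` bins. Longitude
#' +180 wraps onto the -180 column. Latitudes at or north of the grid's
#' northern limit fall outside the grid and return `NA` indices.
#'
#' @param lon,lat Numeric vectors of coordinates in degrees; `lon` in
#'   `[-180, 180]`, `lat` in `[-90, 90]`.
#' @param grid A `grid_spec`.
#' @return A data frame with integer columns `col` and `row` (0-based), `NA`
#'   for points outside the grid.
#' @export
assign_cell <- function(lon, lat, grid) {
  stopifnot(is_grid_spec(grid), length(lon) == length(lat))
  bad <- !is.na(lon) & !is.na(lat) &
    (lon < -180 | lon > 180 | lat < -90 | lat > 90)
  if (any(bad)) {
    stop("coordinates out of range at position(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         " (lon must be in [-180, 180], lat in [-90, 90])", call. = FALSE)
  }
  col <- floor((lon + 180) / grid$lon_width) %% grid$n_cols
  row <- floor((lat - grid$lat_south_limit) / grid$lat_width)
  outside <- row < 0 | row >= grid$n_rows
  # the pole itself belongs to the southernmost row despite half-open bins
  at_pole <- !is.na(lat) & lat == -90 & grid$lat_south_limit == -90
  row[at_pole] <- 0
  outside[at_pole] <- FALSE
  col[outside] <- NA_integer_
  row[outside] <- NA_integer_
  data.frame(col = as.integer(col), row = as.integer(row))
}

#' Spherical areas of grid cells
#'
#' Area of the cell(s) at `(col, row)` using the spherical-zone formula
#' `R^2 * d_lambda * (sin(phi_hi) - sin(phi_lo))`; areas depend only on the
#' row and decrease toward the pole.
#'
#' @param col,row 0-based cell indices (vectorised; recycled to equal length).
#' @param grid A `grid_spec`.
#' @param earth_radius_km Sphere radius; defaults to the grid's.
#' @return Areas in km^2.
#' @export
cell_area <- function(col, row, grid, earth_radius_km = grid$earth_radius_km) {
  stopifnot(is_grid_spec(grid))
  n <- max(length(col), length(row))
  col <- rep_len(as.integer(col), n)
  row <- rep_len(as.integer(row), n)
  ok <- !is.na(col) & !is.na(row)
  if (any(col[ok] < 0 | col[ok] >= grid$n_cols |
          row[ok] < 0 | row[ok] >= grid$n_rows)) {
    stop("cell index out of range for this grid", call. = FALSE)
  }
  phi_lo <- (grid$lat_south_limit + row * grid$lat_width) * pi / 180
  phi_hi <- phi_lo + grid$lat_width * pi / 180
  d_lambda <- grid$lon_width * pi / 180
  earth_radius_km^2 * d_lambda * (sin(phi_hi) - sin(phi_lo))
}

#' Cell centroids and bounds
#'
#' Centroids are the mid-points of the cell's lon/lat intervals (used for
#' facility-distance smoothing and the 60 degrees S traffic mask).
#'
#' @inheritParams cell_area
#' @return `cell_centroid`: data frame with `lon`, `lat`. `cell_bounds`: data
#'   frame with `lon_min`, `lon_max`, `lat_min`, `lat_max`.
#' @export
cell_centroid <- function(col, row, grid) {
  b <- cell_bounds(col, row, grid)
  data.frame(lon = (b$lon_min + b$lon_max) / 2,
             lat = (b$lat_min + b$lat_max) / 2)
}

#' @rdname cell_centroid
#' @export
cell_bounds <- function(col, row, grid) {
  stopifnot(is_grid_spec(grid))
  n <- max(length(col), length(row))
  col <- rep_len(as.integer(col), n)
  row <- rep_len(as.integer(row), n)
  lon_min <- -180 + col * grid$lon_width
  lat_min <- grid$lat_south_limit + row * grid$lat_width
  data.frame(lon_min = lon_min, lon_max = lon_min + grid$lon_width,
             lat_min = lat_min, lat_max = lat_min + grid$lat_width)
}

#' All cells of a grid as a data frame
#'
#' @param grid A `grid_spec`.
#' @return Data frame with `col`, `row`, centroid `lon`/`lat`, `area_km2`,
#'   one row per cell in row-major order (row varying slowest).
#' @export
grid_cells <- function(grid) {
  stopifnot(is_grid_spec(grid))
  cells <- expand.grid(col = seq_len(grid$n_cols) - 1L,
                       row = seq_len(grid$n_rows) - 1L)
  cen <- cell_centroid(cells$col, cells$row, grid)
  cells$lon <- cen$lon
  cells$lat <- cen$lat
  cells$area_km2 <- cell_area(cells$col, cells$row, grid)
  cells
}
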