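#' Gridded value layers
#'
#' A `value_layer` holds one continuous per-cell field on a [build_grid()]
#' grid: a numeric matrix `values` (rows = grid rows from the south, columns
#' = grid columns from -180 degrees) with `NA` marking cells without data,
#' plus a parallel integer matrix `n_obs` counting contributing observations.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix `n_rows x n_cols`, or a single value recycled.
#' @param n_obs Integer matrix of the same shape; defaults to 1 where `values`
#'   is present and 0 where missing.
#' @param name Optional layer name carried through to exports.
#' @return An object of class `value_layer`.
#' @export
value_layer <- function(grid, values = NA_real_, n_obs = NULL, name = NULL) {
  stopifnot(is_grid_spec(grid))
  if (!is.matrix(values)) {
    values <- matrix(as.numeric(values), nrow = grid$n_rows, ncol = grid$n_cols)
  }
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (any(!is.finite(values) & !is.na(values))) {
    stop("layer values must be finite or NA", call. = FALSE)
  }
  if (is.null(n_obs)) {
    n_obs <- matrix(ifelse(is.na(values), 0L, 1L),
                    nrow = grid$n_rows, ncol = grid$n_cols)
  }
  if (!is.matrix(n_obs)) {
    n_obs <- matrix(as.integer(n_obs), nrow = grid$n_rows, ncol = grid$n_cols)
  }
  stopifnot(all(dim(n_obs) == dim(values)))
  structure(list(grid = grid, values = values,
                 n_obs = n_obs, name = name),
            class = "value_layer")
}

#' @export
print.value_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<value_layer%s> %d x %d cells, %d with data",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              nrow(v), ncol(v), sum(!is.na(v))))
  if (any(!is.na(v))) {
    cat(sprintf(", range [%.4g, %.4g]", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

# 1-based matrix index for 0-based (col, row)
cell_mat_index <- function(col, row, grid) {
  cbind(row + 1L, col + 1L)
}

#' Flatten a gridded layer to a data frame
#'
#' @param layer A `value_layer`, `rank_layer`, or `risk_map`.
#' @param drop_missing Drop cells without data?
#' @return Data frame with `col`, `row`, centroid `lon`/`lat`, `value` (and
#'   `n_obs` for value layers).
#' @export
layer_to_df <- function(layer, drop_missing = FALSE) {
  grid <- layer$grid
  vals <- if (inherits(layer, "risk_map")) layer$scores
          else if (inherits(layer, "rank_layer")) layer$ranks
          else layer$values
  df <- grid_cells(grid)
  df$value <- vals[cell_mat_index(df$col, df$row, grid)]
  if (inherits(layer, "value_layer")) {
    df$n_obs <- layer$n_obs[cell_mat_index(df$col, df$row, grid)]
  }
  if (drop_missing) df <- df[!is.na(df$value), , drop = FALSE]
  df
}

#' Fine-resolution raster container
#'
#' A plain lon/lat raster at resolution finer than the analysis grid, as
#' produced by satellite chlorophyll products: `lon` and `lat` are cell-centre
#' coordinate vectors and `values` is a `length(lat) x length(lon)` matrix.
#'
#' @param lon,lat Strictly increasing numeric vectors of cell centres, degrees.
#' @param values Numeric matrix, rows indexed by `lat`, columns by `lon`.
#' @return An object of class `fine_raster`.
#' @export
fine_raster <- function(lon, lat, values) {
  stopifnot(is.numeric(lon), is.numeric(lat), is.matrix(values),
            nrow(values) == length(lat), ncol(values) == length(lon),
            all(diff(lon) > 0), all(diff(lat) > 0))
  structure(list(lon = lon, lat = lat, values = values), class = "fine_raster")
}

#' @export
print.fine_raster <- function(x, ...) {
  cat(sprintf("<fine_raster> %d x %d cells, lon [%g, %g], lat [%g, %g]\n",
              length(x$lat), length(x$lon), min(x$lon), max(x$lon),
              min(x$lat), max(x$lat)))
  invisible(x)
}
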