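# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own aggregation paths: products and explicit roots
# instead of log-space means, per-cell loops instead of tapply, etc.

# Habib-style zero-assimilating geometric mean via product of roots
habib_oracle <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0) return(0)
  (length(pos) / length(x)) * prod(pos^(1 / length(pos)))
}

# per-cell gridding of point samples by explicit loops
grid_samples_oracle <- function(samples, grid, months = 1:3) {
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  mo <- as.integer(format(as.Date(samples$date), "%m"))
  for (row in seq_len(grid$n_rows) - 1) {
    for (col in seq_len(grid$n_cols) - 1) {
      lon_lo <- -180 + col * grid$lon_width
      lat_lo <- grid$lat_south_limit + row * grid$lat_width
      lon <- ifelse(samples$lon == 180, -180, samples$lon)
      sel <- mo %in% months &
        lon >= lon_lo & lon < lon_lo + grid$lon_width &
        samples$lat >= lat_lo & samples$lat < lat_lo + grid$lat_width
      if (any(sel)) out[row + 1, col + 1] <- habib_oracle(samples$value[sel])
    }
  }
  out
}

# threshold-counting rank oracle
rank_oracle <- function(v, scale) {
  tr <- function(x) switch(scale$transform,
                           identity = x, log = log(x), sqrt = sqrt(x),
                           negate = -x)
  vapply(v, function(x) {
    if (is.na(x)) return(NA_integer_)
    if (scale$zero_rule && x == 0) return(1L)
    tx <- tr(x)
    if (tx < scale$outlier_bounds[1]) return(1L)
    if (tx > scale$outlier_bounds[2]) return(5L)
    1L + sum(scale$thresholds <= tx)
  }, integer(1))
}

# available-mean composition oracle on plain matrices
mean_rank_oracle <- function(mats) {
  out <- mats[[1]]
  for (i in seq_along(out)) {
    v <- vapply(mats, function(m) m[[i]], numeric(1))
    out[[i]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

# small grid shared by many tests: 36 x 10 degree cells, 10 cols x 4 rows
small_grid <- function() build_grid(36, 10, -50)
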