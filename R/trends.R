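#' Monthly series container
#'
#' An ordered sequence of strictly consecutive calendar-month values for one
#' grid cell, possibly with missing entries.
#'
#' @param values Numeric vector, one entry per month (NA = missing month).
#' @param start_year,start_month Calendar position of the first entry.
#' @param cell Optional 0-based `c(col, row)` index.
#' @return An object of class `monthly_series`.
#' @export
monthly_series <- function(values, start_year, start_month = 1L, cell = NULL) {
  stopifnot(is.numeric(values), length(values) >= 1,
            start_month %in% 1:12)
  structure(list(values = as.numeric(values),
                 start_year = as.integer(start_year),
                 start_month = as.integer(start_month),
                 cell = cell),
            class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<monthly_series> %d months from %d-%02d, %d missing\n",
              n, x$start_year, x$start_month, sum(is.na(x$values))))
  invisible(x)
}

# calendar month (1-12) and decimal-year time axis of each entry
series_months <- function(series) {
  ((series$start_month - 1L + seq_along(series$values) - 1L) %% 12L) + 1L
}
series_years <- function(series) {
  m0 <- (series$start_month - 1L) + seq_along(series$values) - 1L
  series$start_year + m0 %/% 12L
}
series_time <- function(series) {
  # decimal years at month midpoints
  series_years(series) + (series_months(series) - 0.5) / 12
}

#' Reduce dated values to calendar-month means
#'
#' Step 1 of the per-cell trend method: daily (or irregular) observations in
#' one cell are averaged within calendar months. Months with no data are kept
#' as missing entries so the series stays strictly consecutive.
#'
#' @param dates `Date` vector (or parseable strings).
#' @param values Numeric observations aligned with `dates`.
#' @param cell Optional cell index carried through.
#' @return A [monthly_series()] spanning the first to last observed month.
#' @export
to_monthly <- function(dates, values, cell = NULL) {
  stopifnot(length(dates) == length(values), length(dates) >= 1)
  dates <- as.Date(dates)
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  key <- yr * 12L + (mo - 1L)
  agg <- tapply(values, key, mean, na.rm = TRUE)
  keys <- as.integer(names(agg))
  full <- seq(min(keys), max(keys))
  out <- rep(NA_real_, length(full))
  out[match(keys, full)] <- as.numeric(agg)
  out[is.nan(out)] <- NA_real_
  monthly_series(out, start_year = full[1] %/% 12L,
                 start_month = full[1] %% 12L + 1L, cell = cell)
}

#' Per-calendar-month climatology
#'
#' Step 2: monthly means are averaged per calendar month over a fixed
#' reference window (default 1993-2014) to give a 12-value climatology.
#'
#' @param series A [monthly_series()].
#' @param reference Length-2 integer vector `c(first_year, last_year)`;
#'   `NULL` uses the full series span.
#' @return An object of class `climatology`: list with `month_means` (12
#'   values) and `reference`.
#' @export
compute_climatology <- function(series, reference = c(1993L, 2014L)) {
  stopifnot(inherits(series, "monthly_series"))
  yrs <- series_years(series)
  mos <- series_months(series)
  if (is.null(reference)) reference <- range(yrs)
  in_ref <- yrs >= reference[1] & yrs <= reference[2]
  if (!any(in_ref)) {
    stop("reference period ", reference[1], "-", reference[2],
         " does not overlap the series", call. = FALSE)
  }
  month_means <- vapply(1:12, function(m) {
    v <- series$values[in_ref & mos == m]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    mean(v)
  }, numeric(1))
  if (anyNA(month_means)) {
    stop("no data in the reference window for month(s) ",
         paste(month.abb[which(is.na(month_means))], collapse = ", "),
         call. = FALSE)
  }
  structure(list(month_means = month_means, reference = reference,
                 cell = series$cell),
            class = "climatology")
}

#' Monthly anomalies
#'
#' Step 3: the climatology is differenced from the monthly means, removing
#' the mean seasonal level so that interannual change dominates.
#'
#' @param series A [monthly_series()].
#' @param clim A [compute_climatology()] result.
#' @return A [monthly_series()] of anomalies; missing entries propagate.
#' @export
anomalies <- function(series, clim) {
  stopifnot(inherits(series, "monthly_series"), inherits(clim, "climatology"))
  mos <- series_months(series)
  monthly_series(series$values - clim$month_means[mos],
                 series$start_year, series$start_month, series$cell)
}

# --- moving-average machinery ------------------------------------------------

# symmetric filter with truncated endpoint windows renormalised to sum 1;
# NA-free input assumed
apply_sym_filter <- function(x, w) {
  n <- length(x)
  h <- (length(w) - 1L) %/% 2L
  out <- if (n >= length(w)) {
    as.numeric(stats::filter(x, w, sides = 2))
  } else {
    rep(NA_real_, n) # filter never fits: truncate every window
  }
  # wherever the full window did not fit, truncate it and renormalise
  for (i in which(is.na(out))) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    wi <- w[(lo - i + h + 1L):(hi - i + h + 1L)]
    out[i] <- sum(x[lo:hi] * wi) / sum(wi)
  }
  out
}

ma_2x12 <- function(x) apply_sym_filter(x, c(1, rep(2, 11), 1) / 24)

henderson13_weights <- c(-325, -468, 0, 1100, 2475, 3600, 4032,
                         3600, 2475, 1100, 0, -468, -325) / 16796

henderson13 <- function(x) apply_sym_filter(x, henderson13_weights)

# seasonal moving average applied within each calendar month across years
within_month_ma <- function(x, months, w) {
  out <- numeric(length(x))
  for (m in unique(months)) {
    sel <- which(months == m)
    out[sel] <- apply_sym_filter(x[sel], w)
  }
  out
}

#' Additive X11-style seasonal-trend decomposition
#'
#' Step 4: anomaly series are split into seasonal, trend, and irregular
#' components with the classical additive X11 core: an initial trend from a
#' centred 2x12 moving average; detrending; initial seasonal factors from a
#' 3x3 moving average within each calendar month, re-centred by removing
#' their own 2x12 moving average; deseasonalising; a refined trend from a
#' 13-term Henderson filter; refined seasonal factors from a 3x5 within-month
#' moving average, re-centred the same way; and the irregular as the residual
#' `anomaly - trend - seasonal`, so the three components reconstruct the
#' input exactly. Endpoints use truncated windows renormalised to sum 1,
#' which keeps every component defined over the full span at the cost of some
#' distortion inside the outermost filter half-widths (see [trend_map()]'s
#' `trim_months`).
#'
#' Internal gaps of at most `max_gap` consecutive missing months are filled
#' by linear interpolation before filtering; longer gaps, leading/trailing
#' missing values, or fewer than 36 months are errors.
#'
#' @param anom A [monthly_series()] of anomalies.
#' @param max_gap Longest internal run of missing months to interpolate.
#' @return An object of class `x11_decomposition`: list with numeric vectors
#'   `seasonal`, `trend`, `irregular`, the (gap-filled) `anomaly`, and the
#'   series' `start_year`/`start_month`.
#' @export
x11_decompose <- function(anom, max_gap = 2L) {
  stopifnot(inherits(anom, "monthly_series"))
  x <- anom$values
  cell_lab <- if (is.null(anom$cell)) "" else
    sprintf(" in cell (col %d, row %d)", anom$cell[1], anom$cell[2])
  if (sum(!is.na(x)) < 36L) {
    stop("series too short for decomposition", cell_lab,
         ": need >= 36 non-missing months, have ", sum(!is.na(x)),
         call. = FALSE)
  }
  if (anyNA(x)) {
    na_runs <- rle(is.na(x))
    if (is.na(x[1]) || is.na(x[length(x)])) {
      stop("series", cell_lab, " has missing leading/trailing months; ",
           "trim before decomposing", call. = FALSE)
    }
    if (max(na_runs$lengths[na_runs$values]) > max_gap) {
      stop("series", cell_lab, " has a gap longer than ", max_gap,
           " months; cannot decompose", call. = FALSE)
    }
    x <- stats::approx(seq_along(x), x, xout = seq_along(x))$y
  }
  months <- series_months(anom)

  t1 <- ma_2x12(x)                                  # initial trend
  d1 <- x - t1
  s1 <- within_month_ma(d1, months, c(1, 2, 3, 2, 1) / 9)
  s1 <- s1 - ma_2x12(s1)                            # re-centre
  z <- x - s1                                       # deseasonalised
  trend <- henderson13(z)                           # refined trend
  d2 <- x - trend
  s2 <- within_month_ma(d2, months, c(1, 2, 3, 3, 3, 2, 1) / 15)
  seasonal <- s2 - ma_2x12(s2)                      # refined seasonal
  irregular <- x - trend - seasonal

  structure(list(seasonal = seasonal, trend = trend, irregular = irregular,
                 anomaly = x, start_year = anom$start_year,
                 start_month = anom$start_month, cell = anom$cell),
            class = "x11_decomposition")
}

#' Linear trend with confidence interval and significance
#'
#' Step 5: ordinary least squares of a (decomposed) trend component against
#' time in decimal years. The 95% confidence interval is the two-sided
#' t-interval on the slope and the p-value the slope's two-sided t-test;
#' the significance flag is `p <= alpha`.
#'
#' @param values Numeric trend values.
#' @param time_years Decimal-year time axis, same length.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `trend_result`: list with `gradient`, `ci_low`,
#'   `ci_high` (units per year), `p_value`, `significant`, and `n`.
#' @export
linear_trend <- function(values, time_years, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(time_years)
  values <- values[ok]
  time_years <- time_years[ok]
  if (length(values) < 3) {
    stop("need at least 3 points for a trend fit", call. = FALSE)
  }
  if (stats::sd(time_years) == 0) {
    stop("degenerate time axis: all time points identical", call. = FALSE)
  }
  fit <- stats::lm(values ~ time_years)
  # summary.lm warns on residual-free fits (the legitimate noiseless limit)
  sm <- suppressWarnings(summary(fit))$coefficients
  gradient <- unname(sm["time_years", "Estimate"])
  p_value <- unname(sm["time_years", "Pr(>|t|)"])
  ci <- suppressWarnings(stats::confint(fit, "time_years", level = 0.95))
  if (is.nan(p_value)) p_value <- 1 # perfectly flat residual-free fit of 0 slope
  structure(list(gradient = gradient,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 p_value = p_value,
                 significant = p_value <= alpha,
                 n = length(values)),
            class = "trend_result")
}

#' Gridded monthly (or daily) series
#'
#' Container for a per-cell environmental time series on the analysis grid.
#' Monthly fields store a `[n_time, n_rows, n_cols]` array starting at
#' `start_year`/`start_month`; daily fields store the same array shape with
#' an explicit `dates` vector.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric array `n_time x n_rows x n_cols`.
#' @param start_year,start_month First month (monthly frequency).
#' @param dates `Date` vector of length `n_time` (daily frequency).
#' @return An object of class `series_field` with `freq` "monthly" or "daily".
#' @export
series_field <- function(grid, values, start_year = NULL, start_month = 1L,
                         dates = NULL) {
  stopifnot(is_grid_spec(grid), is.array(values), length(dim(values)) == 3,
            dim(values)[2] == grid$n_rows, dim(values)[3] == grid$n_cols)
  if (!is.null(dates)) {
    stopifnot(length(dates) == dim(values)[1])
    freq <- "daily"
  } else {
    stopifnot(!is.null(start_year))
    freq <- "monthly"
  }
  structure(list(grid = grid, values = values, freq = freq,
                 start_year = start_year, start_month = start_month,
                 dates = dates),
            class = "series_field")
}

#' @export
print.series_field <- function(x, ...) {
  cat(sprintf("<series_field> %s, %d steps, grid %d x %d\n",
              x$freq, dim(x$values)[1], x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

# extract one cell's series as monthly_series (reducing daily if needed)
field_cell_series <- function(field, col, row) {
  v <- field$values[, row + 1L, col + 1L]
  if (field$freq == "daily") {
    if (all(is.na(v))) return(NULL)
    to_monthly(field$dates, v, cell = c(col, row))
  } else {
    monthly_series(v, field$start_year, field$start_month, cell = c(col, row))
  }
}

#' Per-cell linear trend map via the five-step method
#'
#' Chains the full per-cell trend method over a gridded series: (1) monthly
#' means (skipped for already-monthly input), (2) climatology over the
#' reference window, (3) anomalies, (4) X11-style decomposition, (5) OLS
#' trend fit. Cells whose series fail a precondition (too short, gappy, or
#' empty) come out missing, and the failures are collected rather than
#' aborting the map.
#'
#' The regression excludes `trim_months` months at each end of the series:
#' the truncated endpoint filters distort the decomposed trend component
#' within 42 months of each end (the cascade of the 2x12 moving average, the
#' 3x3 within-month average reaching two years, the re-centring average, and
#' the Henderson half-width), so dropping a 48-month run-in leaves exactly
#' the interior where the symmetric filters are unaffected.
#'
#' @param field A [series_field()].
#' @param reference Climatology reference years, default `c(1993, 2014)`;
#'   `NULL` = full span.
#' @param alpha Significance level for the trend flag.
#' @param fit_on Fit the OLS to the decomposed `"trend"` component (default)
#'   or to the `"seasonally_adjusted"` series (trend + irregular).
#' @param trim_months Endpoint run-in excluded from the fit (per end).
#' @return An object of class `trend_field`: list of `n_rows x n_cols`
#'   matrices `gradient`, `ci_low`, `ci_high`, `p_value`, and logical
#'   `significant`, plus the `grid` and a character vector of per-cell
#'   `failures`.
#' @export
trend_map <- function(field, reference = c(1993L, 2014L), alpha = 0.05,
                      fit_on = c("trend", "seasonally_adjusted"),
                      trim_months = 48L) {
  stopifnot(inherits(field, "series_field"))
  fit_on <- match.arg(fit_on)
  grid <- field$grid
  m <- function() matrix(NA_real_, grid$n_rows, grid$n_cols)
  out <- list(gradient = m(), ci_low = m(), ci_high = m(), p_value = m(),
              significant = matrix(NA, grid$n_rows, grid$n_cols),
              grid = grid, failures = character(0))
  for (row in seq_len(grid$n_rows) - 1L) {
    for (col in seq_len(grid$n_cols) - 1L) {
      v <- field$values[, row + 1L, col + 1L]
      if (all(is.na(v))) next
      res <- tryCatch({
        ser <- field_cell_series(field, col, row)
        # drop leading/trailing missing months before decomposition
        pres <- which(!is.na(ser$values))
        if (length(pres) == 0) stop("empty series")
        first <- pres[1]; last <- pres[length(pres)]
        if (first > 1 || last < length(ser$values)) {
          off <- ser$start_month - 1L + first - 1L
          ser <- monthly_series(ser$values[first:last],
                                ser$start_year + off %/% 12L,
                                off %% 12L + 1L, cell = c(col, row))
        }
        clim <- compute_climatology(ser, reference)
        anom <- anomalies(ser, clim)
        dec <- x11_decompose(anom)
        y <- switch(fit_on,
                    trend = dec$trend,
                    seasonally_adjusted = dec$trend + dec$irregular)
        tt <- series_time(ser)
        n <- length(y)
        keep <- seq_len(n) > trim_months & seq_len(n) <= n - trim_months
        if (sum(keep) < 3) stop("series too short after endpoint trimming")
        linear_trend(y[keep], tt[keep], alpha = alpha)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        out$failures <- c(out$failures,
                          sprintf("cell (col %d, row %d): %s", col, row,
                                  conditionMessage(res)))
        next
      }
      out$gradient[row + 1L, col + 1L] <- res$gradient
      out$ci_low[row + 1L, col + 1L] <- res$ci_low
      out$ci_high[row + 1L, col + 1L] <- res$ci_high
      out$p_value[row + 1L, col + 1L] <- res$p_value
      out$significant[row + 1L, col + 1L] <- res$significant
    }
  }
  class(out) <- "trend_field"
  out
}

#' @export
print.trend_field <- function(x, ...) {
  n_ok <- sum(!is.na(x$gradient))
  cat(sprintf("<trend_field> %d cells fitted, %d significant, %d failures\n",
              n_ok, sum(x$significant, na.rm = TRUE), length(x$failures)))
  invisible(x)
}
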