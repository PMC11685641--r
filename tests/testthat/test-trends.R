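make_series <- function(values, start_year = 2000, start_month = 1) {
  monthly_series(values, start_year, start_month)
}

test_that("daily values reduce to calendar-month means with gaps preserved", {
  d_jan <- seq(as.Date("2001-01-01"), as.Date("2001-01-31"), by = "day")
  s <- to_monthly(d_jan, rep(3.2, 31))
  expect_equal(s$values, 3.2)
  # January and March observed, February empty -> NA kept in sequence
  d <- c(d_jan, seq(as.Date("2001-03-01"), as.Date("2001-03-10"), by = "day"))
  s <- to_monthly(d, c(rep(1, 31), rep(5, 10)))
  expect_equal(s$values, c(1, NA, 5))
  # random daily series vs brute-force month grouping
  set.seed(21)
  dates <- as.Date("2003-01-01") + sample.int(900, 500)
  vals <- rnorm(500)
  s <- to_monthly(dates, vals)
  key <- format(dates, "%Y-%m")
  expected <- tapply(vals, key, mean)
  got <- s$values[!is.na(s$values)]
  expect_equal(as.numeric(got),
               as.numeric(expected[order(names(expected))]),
               tolerance = 1e-12)
})

test_that("climatology averages each calendar month over the reference window", {
  s <- make_series(rep(2.5, 120), 1990)
  clim <- compute_climatology(s, c(1993, 1998))
  expect_equal(clim$month_means, rep(2.5, 12))
  cyc <- sin(2 * pi * (1:12) / 12)
  s2 <- make_series(rep(cyc, 10), 1990)
  expect_equal(compute_climatology(s2, c(1990, 1999))$month_means, cyc)
  # trended series vs brute-force per-month averages
  set.seed(22)
  v <- 0.01 * (1:240) + rnorm(240)
  s3 <- make_series(v, 1990)
  clim3 <- compute_climatology(s3, c(1995, 2005))
  yrs <- rep(1990:2009, each = 12)
  mos <- rep(1:12, 20)
  expected <- vapply(1:12, function(m) {
    mean(v[yrs >= 1995 & yrs <= 2005 & mos == m])
  }, numeric(1))
  expect_equal(clim3$month_means, expected, tolerance = 1e-12)
  expect_error(compute_climatology(s, c(2050, 2060)), "does not overlap")
})

test_that("a month absent from the reference window is reported by name", {
  v <- rep(1, 48)
  v[seq(2, 48, by = 12)] <- NA # every February missing
  expect_error(compute_climatology(make_series(v, 2000), c(2000, 2003)),
               "Feb")
})

test_that("anomalies subtract the climatology month-wise", {
  cyc <- sin(2 * pi * (1:12) / 12)
  s <- make_series(rep(cyc, 5), 2000)
  clim <- compute_climatology(s, c(2000, 2004))
  expect_equal(anomalies(s, clim)$values, rep(0, 60), tolerance = 1e-12)
  s_off <- make_series(rep(cyc, 5) + 1.5, 2000)
  expect_equal(anomalies(s_off, clim)$values, rep(1.5, 60), tolerance = 1e-12)
  set.seed(23)
  v <- rnorm(60)
  v[10] <- NA
  s_r <- make_series(v, 2000)
  a <- anomalies(s_r, clim)$values
  expect_equal(a, v - clim$month_means[rep(1:12, 5)], tolerance = 1e-12)
  expect_true(is.na(a[10]))
})

test_that("a pure ramp decomposes into trend with negligible seasonality", {
  n <- 240
  b <- 0.01
  x <- 2 + b * (1:n)
  dec <- x11_decompose(make_series(x, 2000))
  # away from the truncated endpoint windows there is nothing seasonal
  i <- 85:(n - 84)
  expect_lt(max(abs(dec$seasonal[i])), 1e-6 * b * n)
  j <- 43:(n - 42) # beyond the trend filters' run-in
  expect_equal(dec$trend[j], x[j], tolerance = 1e-9)
})

test_that("ramp plus exact 12-period sinusoid is recovered component-wise", {
  n <- 240
  t <- 1:n
  trend_true <- 0.5 + 0.002 * t
  seas_true <- 0.8 * sin(2 * pi * t / 12)
  dec <- x11_decompose(make_series(trend_true + seas_true, 1990))
  i <- 85:(n - 84) # interior untouched by any truncated endpoint window
  expect_equal(dec$seasonal[i], seas_true[i], tolerance = 0.01)
  expect_equal(dec$trend[i], trend_true[i], tolerance = 0.01)
  expect_lt(max(abs(dec$irregular[i])), 1e-10)
})

test_that("the decomposition reconstructs any input exactly and the seasonal sums to zero", {
  set.seed(24)
  n <- 240
  x <- 0.003 * (1:n) + sin(2 * pi * (1:n) / 12) + rnorm(n, 0, 0.3)
  dec <- x11_decompose(make_series(x, 1990))
  expect_equal(dec$seasonal + dec$trend + dec$irregular, x,
               tolerance = 1e-12)
  # deterministic ramp+sinusoid: every 12-month window away from endpoints
  y <- 0.003 * (1:n) + sin(2 * pi * (1:n) / 12)
  dy <- x11_decompose(make_series(y, 1990))
  sums <- vapply(85:(n - 95), function(j) sum(dy$seasonal[j:(j + 11)]),
                 numeric(1))
  expect_lt(max(abs(sums)), 1e-8)
})

test_that("short, gappy, or unpadded series are rejected with cell context", {
  expect_error(x11_decompose(make_series(rnorm(30), 2000)), "36")
  v <- rnorm(60)
  v[20:25] <- NA
  expect_error(x11_decompose(monthly_series(v, 2000, cell = c(3, 1))),
               "gap.*col 3, row 1|col 3, row 1.*gap")
  v2 <- c(NA, rnorm(59))
  expect_error(x11_decompose(make_series(v2, 2000)), "leading")
  # a gap of <= 2 months is interpolated, not fatal
  v3 <- rnorm(60)
  v3[30] <- NA
  expect_silent(x11_decompose(make_series(v3, 2000)))
})

test_that("linear_trend recovers noiseless slopes and flags them significant", {
  t <- 2000 + (1:120) / 12
  res <- linear_trend(1 + 0.004 * t, t)
  expect_equal(res$gradient, 0.004, tolerance = 1e-10)
  expect_lt(res$p_value, 1e-10)
  expect_true(res$significant)
  expect_true(res$ci_low <= res$gradient && res$gradient <= res$ci_high)
  # constant series: zero gradient, not significant
  res0 <- linear_trend(rep(2, 60), 2000 + (1:60) / 12)
  expect_equal(res0$gradient, 0)
  expect_false(res0$significant)
  expect_error(linear_trend(rnorm(10), rep(1, 10)), "degenerate")
  expect_error(linear_trend(rnorm(2), 1:2), "at least 3")
})

test_that("the 95% interval covers a true slope at its nominal rate", {
  set.seed(25)
  t <- (1:120) / 12
  covered <- vapply(1:500, function(i) {
    y <- 0.004 * t + rnorm(120, 0, 0.05)
    r <- linear_trend(y, t)
    r$ci_low <= 0.004 && 0.004 <= r$ci_high
  }, logical(1))
  expect_gt(mean(covered), 0.92)
  expect_lt(mean(covered), 0.98)
})

test_that("an all-constant field yields zero gradients, none significant", {
  g <- small_grid()
  vals <- array(1.7, dim = c(120, g$n_rows, g$n_cols))
  fld <- series_field(g, vals, start_year = 2000)
  tm <- trend_map(fld, reference = NULL, trim_months = 12)
  expect_true(all(tm$gradient == 0))
  expect_false(any(tm$significant))
})

test_that("monthly input equals the trend map of its daily expansion", {
  g <- build_grid(120, 20, -50)
  tf <- gen_trend_field(g, seed = 26, magnitude = c(0.005, 0.02))
  monthly <- gen_env_series(g, tf, seed = 27, start_year = 2000,
                            end_year = 2014, sigma = 0)
  # expand each month's value over its days: to_monthly must invert this
  dates <- seq(as.Date("2000-01-01"), as.Date("2014-12-31"), by = "day")
  mkey <- (as.integer(format(dates, "%Y")) - 2000) * 12 +
    as.integer(format(dates, "%m"))
  daily_vals <- monthly$values[mkey, , , drop = FALSE]
  daily <- series_field(g, daily_vals, dates = dates)
  tm_m <- trend_map(monthly, reference = c(2000, 2014))
  tm_d <- trend_map(daily, reference = c(2000, 2014))
  expect_equal(tm_d$gradient, tm_m$gradient, tolerance = 1e-12)
  expect_equal(tm_d$p_value, tm_m$p_value, tolerance = 1e-9)
})

test_that("shifting the climatology window leaves fitted gradients unchanged", {
  g <- build_grid(120, 20, -50)
  tf <- gen_trend_field(g, seed = 28)
  fld <- gen_env_series(g, tf, seed = 29, start_year = 1990, end_year = 2014,
                        sigma = 0.05)
  tm_a <- trend_map(fld, reference = c(1993, 2010))
  tm_b <- trend_map(fld, reference = c(1995, 2005))
  expect_equal(tm_a$gradient, tm_b$gradient, tolerance = 1e-10)
})

test_that("cells with unusable series are collected as failures, not fatal", {
  g <- build_grid(120, 20, -50)
  vals <- array(rnorm(120 * g$n_rows * g$n_cols),
                dim = c(120, g$n_rows, g$n_cols))
  vals[, 1, 1] <- NA               # empty cell -> silently missing
  vals[40:80, 1, 2] <- NA          # long gap -> failure entry
  fld <- series_field(g, vals, start_year = 2000)
  tm <- trend_map(fld, reference = NULL, trim_months = 12)
  expect_true(is.na(tm$gradient[1, 1]))
  expect_true(is.na(tm$gradient[1, 2]))
  expect_true(any(grepl("col 1, row 0", tm$failures)))
  expect_false(is.na(tm$gradient[2, 2]))
})
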