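test_that("all generators are pure functions of parameters and seed", {
  g <- small_grid()
  f1 <- gen_facilities(30, seed = 7, grid = g)
  f2 <- gen_facilities(30, seed = 7, grid = g)
  expect_identical(f1, f2)
  s1 <- gen_ship_traffic(f1$facilities, g, years = 2014:2015, seed = 7)
  s2 <- gen_ship_traffic(f1$facilities, g, years = 2014:2015, seed = 7)
  expect_identical(s1, s2)
  k1 <- gen_krill_samples(200, seed = 7, grid = g)
  expect_identical(k1, gen_krill_samples(200, seed = 7, grid = g))
  c1 <- gen_chl_raster(seed = 7, grid = g, fine_resolution = 1)
  expect_identical(c1, gen_chl_raster(seed = 7, grid = g, fine_resolution = 1))
  tf <- gen_trend_field(g, seed = 7)
  e1 <- gen_env_series(g, tf, seed = 7, start_year = 2000, end_year = 2004)
  expect_identical(e1$values,
                   gen_env_series(g, tf, seed = 7, start_year = 2000,
                                  end_year = 2004)$values)
  # different seeds give different draws
  expect_false(identical(f1$facilities$lon,
                         gen_facilities(30, seed = 8, grid = g)$facilities$lon))
  # the caller's RNG stream is not disturbed
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(gen_facilities(10, seed = 7, grid = g))
  expect_identical(rnorm(1), before)
})

test_that("facility populations follow the configured log-normal", {
  g <- small_grid()
  f <- gen_facilities(10000, seed = 8, grid = g,
                      pop_median = 20, pop_sdlog = 1.2)
  pops <- f$facilities$peak_population
  expect_true(all(pops >= 0))
  lp <- log(pops[pops > 0])
  # rounding to integers biases the small tail slightly; 3 SE on the rest
  se_m <- 1.2 / sqrt(length(lp))
  expect_lt(abs(mean(lp) - log(20)), 3 * se_m + 0.05)
  expect_lt(abs(sd(lp) - 1.2), 0.1)
  expect_setequal(levels(population_category(pops)),
                  c("0-9", "10-24", "25-49", "50-99", ">=100"))
  f1 <- gen_facilities(1, seed = 9, grid = g)
  expect_equal(nrow(f1$facilities), 1L)
  idx <- assign_cell(f1$facilities$lon, f1$facilities$lat, g)
  expect_equal(c(idx$col, idx$row), f1$truth$hotspot_cell)
})

test_that("ship traffic is maximal at an isolated facility with no background", {
  g <- small_grid()
  fac <- data.frame(lon = -100, lat = -75, peak_population = 500)
  rec <- gen_ship_traffic(fac, g, years = 2014:2016, seed = 10,
                          background = 0, intensity = 80)
  persons <- c(fishing = 1, tourist = 1, "cargo/supply" = 1,
               research = 1, other = 1)
  out <- ship_person_days(rec, persons, g)
  idx <- assign_cell(fac$lon, fac$lat, g)
  expect_equal(which.max(out$total$values),
               idx$col * g$n_rows + idx$row + 1L)
})

test_that("simulated ship-day totals agree with the analytic expectation", {
  g <- small_grid()
  fac <- data.frame(lon = -100, lat = -75, peak_population = 100)
  # analytic expectation in the facility's own cell: the decay acts on the
  # facility-to-centroid distance, not zero
  idx <- assign_cell(fac$lon, fac$lat, g)
  cen <- cell_centroid(idx$col, idx$row, g)
  d0 <- as.numeric(geosphere::distm(cbind(fac$lon, fac$lat),
                                    cbind(cen$lon, cen$lat),
                                    fun = geosphere::distHaversine)) /
    6378137 * g$earth_radius_km
  lam <- 0.2 + 60 * exp(-d0 / 400)
  totals <- vapply(1:200, function(s) {
    rec <- gen_ship_traffic(fac, g, years = 2014, seed = s)
    sum(rec$days[rec$col == idx$col & rec$row == idx$row])
  }, numeric(1))
  se <- sqrt(lam / 200)
  expect_lt(abs(mean(totals) - lam), 3 * se)
})

test_that("krill samples honour zero inflation and converge to the cell truth", {
  g <- small_grid()
  all_zero <- gen_krill_samples(300, seed = 11, grid = g, zero_inflation = 1)
  expect_true(all(all_zero$samples$value == 0))
  dense <- gen_krill_samples(30000, seed = 12, grid = g, zero_inflation = 0,
                             hotspot_frac = 0)
  layer <- grid_point_samples(dense$samples, g, month_filter = NULL)
  well_sampled <- !is.na(layer$values) & layer$n_obs >= 200
  expect_gt(sum(well_sampled), 5)
  rel_err <- abs(layer$values[well_sampled] /
                   dense$truth$mean_field[well_sampled] - 1)
  expect_lt(stats::median(rel_err), 0.10)
  # sampling dates are restricted to January-March
  mo <- as.integer(format(dense$samples$date, "%m"))
  expect_true(all(mo %in% 1:3))
})

test_that("chlorophyll raster reproduces the configured nearshore/offshore contrast", {
  g <- small_grid()
  r <- gen_chl_raster(seed = 13, grid = g, fine_resolution = 0.5,
                      nearshore = 2, offshore = 0.2, noise_sdlog = 0.1)
  layer <- regrid_raster_geomean(r, g)
  south <- exp(mean(log(layer$values[1, ])))  # coastal rows
  north <- exp(mean(log(layer$values[g$n_rows, ])))
  expect_gt(south / north, 5)
  # northern rows sit in the transition tail, a little above the offshore floor
  expect_lt(abs(north / 0.2 - 1), 0.5)
})

test_that("environmental series carry the injected trend in the noiseless limit", {
  g <- build_grid(120, 20, -50)
  tf <- gen_trend_field(g, seed = 14, magnitude = c(0.004, 0.004))
  expect_true(all(abs(tf) == 0.004))
  # with zero amplitude and noise the series is exactly linear in time
  fld <- gen_env_series(g, tf, seed = 15, start_year = 2000, end_year = 2009,
                        sigma = 0, amplitude = 0)
  v <- fld$values[, 1, 1]
  t <- (seq_along(v) - 0.5) / 12
  slope <- coef(lm(v ~ t))[2]
  expect_equal(unname(slope), tf[1, 1], tolerance = 1e-10)
})

test_that("the input bundle co-locates facility cluster, traffic, and krill maxima", {
  bundle <- gen_input_bundle(seed = 3, grid = build_grid(),
                             n_facilities = 60, n_krill = 800,
                             chl_resolution = 1)
  hc <- bundle$truth$hotspot_cell
  # krill truth maximal at the hotspot cell
  expect_equal(which.max(bundle$truth$krill_field),
               (hc[1]) * nrow(bundle$truth$krill_field) + hc[2] + 1)
  # facility population maximal in the hotspot cell
  g <- build_grid()
  idx <- assign_cell(bundle$facilities$lon, bundle$facilities$lat, g)
  pop_by_cell <- tapply(bundle$facilities$peak_population,
                        idx$row * g$n_cols + idx$col, sum)
  expect_equal(as.integer(names(which.max(pop_by_cell))),
               hc[2] * g$n_cols + hc[1])
})
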