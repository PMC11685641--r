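test_that("facility person-day formulas follow the 365p / 182.5p convention", {
  expect_equal(annual_person_days("year-round", 1), 365)
  expect_equal(annual_person_days("seasonal", 1), 182.5)
  expect_equal(annual_person_days("year-round", 0), 0)
  expect_equal(annual_person_days(c("year-round", "seasonal"), c(80, 80)),
               c(29200, 14600))
  fac <- data.frame(seasonality = "seasonal", peak_population = 40)
  expect_equal(annual_person_days(fac), 7300)
  expect_error(annual_person_days("summer-only", 10), "summer-only")
})

test_that("seasonal weighting halves the effective population", {
  expect_equal(seasonally_weighted_population("year-round", 100), 100)
  expect_equal(seasonally_weighted_population("seasonal", 100), 50)
  expect_equal(seasonally_weighted_population("seasonal", 0), 0)
})

test_that("ship person-days multiply, group, and average across years", {
  g <- small_grid()
  persons <- c(tourist = 20, fishing = 30)
  rec <- data.frame(vessel_id = "V1", vessel_type = "tourist",
                    year = 2014, col = 2L, row = 1L, days = 10)
  out <- ship_person_days(rec, persons, g)
  expect_equal(out$total$values[2, 3], 200)
  expect_equal(sum(out$total$values), 200)
  # a year with no ship time still counts in the interannual mean
  rec2 <- rbind(rec, data.frame(vessel_id = "V2", vessel_type = "tourist",
                                year = 2015, col = 5L, row = 0L, days = 1))
  out2 <- ship_person_days(rec2, persons, g)
  expect_equal(out2$total$values[2, 3], 100)
  expect_error(ship_person_days(
    data.frame(vessel_id = "V", vessel_type = "yacht", year = 2014,
               col = 0L, row = 0L, days = 1), persons, g), "yacht")
})

test_that("random ship tables match a brute-force group-sum-mean oracle", {
  g <- small_grid()
  set.seed(31)
  types <- c("fishing", "tourist", "cargo/supply", "research", "other")
  persons <- c(fishing = 40, tourist = 150, "cargo/supply" = 25,
               research = 50, other = 20)
  n <- 400
  rec <- data.frame(vessel_id = sprintf("V%03d", sample(50, n, TRUE)),
                    vessel_type = sample(types, n, TRUE),
                    year = sample(2014:2018, n, TRUE),
                    col = sample(0:(g$n_cols - 1), n, TRUE),
                    row = sample(0:(g$n_rows - 1), n, TRUE),
                    days = round(runif(n, 0, 30), 1))
  out <- ship_person_days(rec, persons, g)
  n_years <- length(unique(rec$year))
  for (ty in types) {
    oracle <- matrix(0, g$n_rows, g$n_cols)
    sub <- rec[rec$vessel_type == ty, ]
    for (i in seq_len(nrow(sub))) {
      oracle[sub$row[i] + 1, sub$col[i] + 1] <-
        oracle[sub$row[i] + 1, sub$col[i] + 1] +
        sub$days[i] * persons[[ty]] / n_years
    }
    expect_equal(out$by_type[[ty]]$values, oracle, tolerance = 1e-12)
  }
  # the total layer is exactly the sum of the five type layers
  expect_equal(out$total$values,
               Reduce(`+`, lapply(out$by_type, function(l) l$values)))
})

test_that("cells containing facilities use population over cell area", {
  g <- small_grid()
  fac <- data.frame(lon = -100, lat = -75, peak_population = 100)
  layer <- effective_population_density(fac, g)
  idx <- assign_cell(fac$lon, fac$lat, g)
  area <- cell_area(idx$col, idx$row, g)
  expect_equal(layer$values[idx$row + 1, idx$col + 1], 100 / area * 1e4)
  expect_true(all(layer$values >= 0))
})

test_that("remote cells follow the inverse-square smoothing law", {
  g <- small_grid()
  fac <- data.frame(lon = 0, lat = -55, peak_population = 200)
  layer <- effective_population_density(fac, g)
  cells <- grid_cells(g)
  d <- as.numeric(geosphere::distm(
    cbind(0, -55), cbind(cells$lon, cells$lat),
    fun = geosphere::distHaversine)) / 6378137 * g$earth_radius_km
  idx <- assign_cell(0, -55, g)
  remote <- !(cells$col == idx$col & cells$row == idx$row)
  got <- layer$values[cbind(cells$row + 1, cells$col + 1)][remote]
  expect_equal(got, 1e4 * 200 / (pi * d[remote]^2), tolerance = 1e-10)
  # doubling the distance divides a contribution by four
  r <- got * d[remote]^2
  expect_equal(max(r), min(r), tolerance = 1e-10)
  # strictly decreasing wherever distance strictly increases
  o <- order(d[remote])
  strictly_farther <- diff(d[remote][o]) > 1e-9
  expect_true(all(diff(got[o])[strictly_farther] < 0))
})

test_that("the areal-product variant decays with the fourth power", {
  g <- small_grid()
  fac <- data.frame(lon = 0, lat = -55, peak_population = 200)
  layer <- effective_population_density(fac, g, method = "areal_product")
  cells <- grid_cells(g)
  d <- as.numeric(geosphere::distm(
    cbind(0, -55), cbind(cells$lon, cells$lat),
    fun = geosphere::distHaversine)) / 6378137 * g$earth_radius_km
  idx <- assign_cell(0, -55, g)
  j <- which(cells$col == (idx$col + 5) %% g$n_cols & cells$row == idx$row)
  expect_equal(layer$values[cells$row[j] + 1, cells$col[j] + 1],
               1e4 * 200 / (pi * d[j]^2) * cells$area_km2[j] / (pi * d[j]^2),
               tolerance = 1e-10)
})

test_that("facility layers are additive on facility-free cells and zero without facilities", {
  g <- small_grid()
  empty <- effective_population_density(
    data.frame(lon = numeric(0), lat = numeric(0),
               peak_population = numeric(0)), g)
  expect_true(all(empty$values == 0))
  set.seed(32)
  fac <- data.frame(lon = runif(8, -180, 180), lat = runif(8, -80, -55),
                    peak_population = sample(5:200, 8))
  a <- effective_population_density(fac[1:4, ], g)
  b <- effective_population_density(fac[5:8, ], g)
  u <- effective_population_density(fac, g)
  idx <- assign_cell(fac$lon, fac$lat, g)
  occupied <- unique(idx$row * g$n_cols + idx$col)
  cells <- grid_cells(g)
  free <- !(cells$row * g$n_cols + cells$col) %in% occupied
  mi <- cbind(cells$row + 1, cells$col + 1)[free, ]
  expect_equal(u$values[mi], a$values[mi] + b$values[mi], tolerance = 1e-12)
})

test_that("seasonal weighting feeds the density proxy when enabled", {
  g <- small_grid()
  fac <- data.frame(lon = 10, lat = -75, peak_population = 100,
                    seasonality = "seasonal")
  plain <- effective_population_density(fac, g)
  weighted <- effective_population_density(fac, g, seasonal_weighting = TRUE)
  expect_equal(weighted$values, plain$values / 2, tolerance = 1e-12)
})
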