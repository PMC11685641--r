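#' Synthetic pipeline inputs with known ground truth
#'
#' The generators in this module emit inputs with the statistical structure
#' of the pipeline's source datasets — zero-inflated log-normal krill
#' densities sampled in January-March, smooth coastal chlorophyll gradients
#' with log-normal noise, monthly environmental series with seasonality,
#' linear trends and AR(1) noise, log-normally distributed facility
#' populations clustered along the coast, and ship traffic concentrated near
#' facilities — together with the ground truth they were drawn from, so every
#' stage of the pipeline can be verified at desk scale. All generators are
#' pure functions of their parameters and `seed`. One engineered region
#' co-locates the facility cluster, the traffic maximum, and the biota
#' maximum, giving end-to-end hotspot-recovery tests a known answer.
#'
#' @name synthetic
NULL

# deterministic local RNG: never disturbs the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# the engineered hotspot cell: northern Antarctic Peninsula analogue
default_cluster <- list(lon = -58, lat = -64)

#' Cells of the engineered hotspot region
#'
#' The planted joint maximum is a region, not a single cell: the
#' distance-smoothed traffic and facility-density fields spread the
#' engineered peak into the cells adjacent to the cluster cell. This helper
#' returns the cluster cell and its (up to) eight grid neighbours, with
#' longitude wrap-around.
#'
#' @param hotspot_cell 0-based `c(col, row)` of the cluster cell.
#' @param grid A `grid_spec`.
#' @return Data frame of 0-based `col`, `row` indices.
#' @export
hotspot_region <- function(hotspot_cell, grid) {
  nb <- expand.grid(dc = -1:1, dr = -1:1)
  col <- (hotspot_cell[1] + nb$dc) %% grid$n_cols
  row <- hotspot_cell[2] + nb$dr
  keep <- row >= 0 & row < grid$n_rows
  data.frame(col = as.integer(col[keep]), row = as.integer(row[keep]))
}

#' Generate a synthetic facility catalogue
#'
#' Facilities are placed in a coastal latitude band with one engineered
#' dense cluster (default near the Antarctic Peninsula); peak populations
#' are log-normal (default median 20, sigma_log 1.2) truncated to integers,
#' and seasonality is a year-round/seasonal mix.
#'
#' @param n Number of facilities.
#' @param seed Integer seed.
#' @param grid A `grid_spec`.
#' @param cluster_frac Fraction of facilities placed in the cluster cell.
#' @param cluster_lon,cluster_lat Cluster location, degrees.
#' @param pop_median,pop_sdlog Log-normal population parameters.
#' @param frac_year_round Probability a facility is year-round.
#' @param coastal_lat Latitude band for non-cluster facilities.
#' @return List with `facilities` (data frame: `name`, `lon`, `lat`,
#'   `facility_type`, `seasonality`, `peak_population`) and `truth` (list
#'   with `hotspot_cell`, the 0-based `c(col, row)` of the cluster).
#' @export
gen_facilities <- function(n = 112, seed = 1, grid = build_grid(),
                           cluster_frac = 0.4,
                           cluster_lon = default_cluster$lon,
                           cluster_lat = default_cluster$lat,
                           pop_median = 20, pop_sdlog = 1.2,
                           frac_year_round = 0.4,
                           coastal_lat = c(-78, -63)) {
  stopifnot(n >= 1)
  with_seed(seed, {
    n_cluster <- max(1L, round(n * cluster_frac))
    if (n == 1) n_cluster <- 1L
    n_rest <- n - n_cluster
    ccell <- assign_cell(cluster_lon, cluster_lat, grid)
    cb <- cell_bounds(ccell$col, ccell$row, grid)
    lon <- c(stats::runif(n_cluster, cb$lon_min, cb$lon_max),
             stats::runif(n_rest, -180, 180))
    lat <- c(stats::runif(n_cluster, cb$lat_min, cb$lat_max),
             stats::runif(n_rest, coastal_lat[1], coastal_lat[2]))
    types <- c("research station", "camp", "airfield camp",
               "refuge", "depot", "laboratory")
    facilities <- data.frame(
      name = sprintf("synthetic_facility_%03d", seq_len(n)),
      lon = lon, lat = lat,
      facility_type = sample(types, n, replace = TRUE,
                             prob = c(0.4, 0.25, 0.1, 0.1, 0.1, 0.05)),
      seasonality = ifelse(stats::runif(n) < frac_year_round,
                           "year-round", "seasonal"),
      peak_population = pmax(0L, as.integer(round(
        stats::rlnorm(n, meanlog = log(pop_median), sdlog = pop_sdlog)))),
      stringsAsFactors = FALSE
    )
    list(facilities = facilities,
         truth = list(hotspot_cell = c(ccell$col, ccell$row), seed = seed))
  })
}

#' Population category of a facility
#'
#' The five peak-population categories used to group facilities.
#'
#' @param peak_population Nonnegative integer vector.
#' @return Ordered factor with levels `0-9`, `10-24`, `25-49`, `50-99`,
#'   `>=100`.
#' @export
population_category <- function(peak_population) {
  stopifnot(all(peak_population >= 0))
  cut(peak_population, breaks = c(-Inf, 9, 24, 49, 99, Inf),
      labels = c("0-9", "10-24", "25-49", "50-99", ">=100"),
      ordered_result = TRUE)
}

#' Generate synthetic ship-traffic records
#'
#' Per-cell expected ship-days decay exponentially with distance from the
#' facilities (scaled by facility population) on top of a uniform
#' background, so traffic concentrates near the facility cluster. Day counts
#' are Poisson per vessel-type, cell, and year, split over the five vessel
#' types. Records are emitted only for cells south of `lat_limit`, matching
#' the coverage of the human-activity maps.
#'
#' @param facilities Facility data frame (see [gen_facilities()]).
#' @param grid A `grid_spec`.
#' @param years Calendar years to simulate.
#' @param seed Integer seed.
#' @param background Background expected ship-days per cell-year.
#' @param decay_km Exponential decay scale of traffic with distance.
#' @param intensity Ship-days per cell-year at a facility of population 100.
#' @param type_shares Named shares over the five vessel types (sum 1).
#' @param lat_limit Northern limit of ship data coverage.
#' @return Data frame of ship records: `vessel_id`, `vessel_type`, `year`,
#'   `col`, `row`, `days`.
#' @export
gen_ship_traffic <- function(facilities, grid = build_grid(),
                             years = 2014:2018, seed = 1,
                             background = 0.2, decay_km = 400,
                             intensity = 60,
                             type_shares = c(fishing = 0.3, tourist = 0.3,
                                             "cargo/supply" = 0.2,
                                             research = 0.15, other = 0.05),
                             lat_limit = -60) {
  stopifnot(nrow(facilities) > 0, abs(sum(type_shares) - 1) < 1e-9)
  with_seed(seed, {
    cells <- grid_cells(grid)
    cells <- cells[cells$lat < lat_limit, , drop = FALSE]
    d <- geosphere::distm(cbind(facilities$lon, facilities$lat),
                          cbind(cells$lon, cells$lat),
                          fun = geosphere::distHaversine) /
      6378137 * grid$earth_radius_km
    lambda <- background + intensity *
      colSums((facilities$peak_population / 100) * exp(-d / decay_km))
    recs <- list()
    for (ty in names(type_shares)) {
      for (yr in years) {
        days <- stats::rpois(nrow(cells), lambda * type_shares[[ty]])
        keep <- days > 0
        if (!any(keep)) next
        recs[[length(recs) + 1L]] <- data.frame(
          vessel_id = sprintf("SYN-%s-%d-%d", abbreviate(ty, 4), yr,
                              which(keep)),
          vessel_type = ty, year = yr,
          col = cells$col[keep], row = cells$row[keep],
          days = days[keep], stringsAsFactors = FALSE)
      }
    }
    if (length(recs) == 0) {
      return(data.frame(vessel_id = character(0), vessel_type = character(0),
                        year = integer(0), col = integer(0), row = integer(0),
                        days = numeric(0)))
    }
    do.call(rbind, recs)
  })
}

# per-cell true mean krill density field (individuals m^-2), coastal enhanced
krill_truth_field <- function(grid, offshore = 3, coastal = 30,
                              coastal_lat = -63, hotspot_boost = 4,
                              hotspot_cell = NULL) {
  cells <- grid_cells(grid)
  truth <- matrix(offshore, grid$n_rows, grid$n_cols)
  truth[cell_mat_index(cells$col, cells$row, grid)] <-
    ifelse(cells$lat < coastal_lat, coastal, offshore)
  if (!is.null(hotspot_cell)) {
    truth[hotspot_cell[2] + 1L, hotspot_cell[1] + 1L] <-
      coastal * hotspot_boost
  }
  truth
}

#' Generate synthetic krill net samples
#'
#' Point samples around a per-cell true mean-density field with coastal
#' enhancement and an engineered maximum in the hotspot cell. Each sample is
#' zero with probability `zero_inflation`, otherwise log-normal with
#' geometric mean equal to the cell truth (so per-cell zero-free geometric
#' means converge to the truth). Dates are uniform over January-March across
#' `years`.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param grid A `grid_spec`.
#' @param zero_inflation Probability a sample records zero krill.
#' @param sdlog Log-scale spread of positive densities.
#' @param years Sampling years.
#' @param hotspot_frac Fraction of samples placed in the hotspot cell.
#' @param hotspot_cell 0-based `c(col, row)`; default the engineered cluster.
#' @param sample_lat Latitude band sampled outside the hotspot.
#' @return List with `samples` (data frame `lon`, `lat`, `date`, `value`)
#'   and `truth` (list with the `mean_field` matrix and `hotspot_cell`).
#' @export
gen_krill_samples <- function(n = 2000, seed = 1, grid = build_grid(),
                              zero_inflation = 0.2, sdlog = 1,
                              years = 1990:2010, hotspot_frac = 0.1,
                              hotspot_cell = NULL,
                              sample_lat = c(-78, -48)) {
  stopifnot(n >= 1, zero_inflation >= 0, zero_inflation <= 1)
  if (is.null(hotspot_cell)) {
    hc <- assign_cell(default_cluster$lon, default_cluster$lat, grid)
    hotspot_cell <- c(hc$col, hc$row)
  }
  truth <- krill_truth_field(grid, hotspot_cell = hotspot_cell)
  with_seed(seed, {
    n_hot <- round(n * hotspot_frac)
    hb <- cell_bounds(hotspot_cell[1], hotspot_cell[2], grid)
    lon <- c(stats::runif(n_hot, hb$lon_min, hb$lon_max),
             stats::runif(n - n_hot, -180, 180))
    lat <- c(stats::runif(n_hot, hb$lat_min, hb$lat_max),
             stats::runif(n - n_hot, sample_lat[1],
                          min(sample_lat[2], grid$lat_north_limit)))
    idx <- assign_cell(lon, lat, grid)
    mu <- truth[cell_mat_index(idx$col, idx$row, grid)]
    value <- ifelse(stats::runif(n) < zero_inflation, 0,
                    stats::rlnorm(n, meanlog = log(mu), sdlog = sdlog))
    yr <- sample(years, n, replace = TRUE)
    doy <- sample.int(90, n, replace = TRUE) # Jan 1 .. Mar 30/31
    date <- as.Date(sprintf("%d-01-01", yr)) + (doy - 1)
    list(samples = data.frame(lon = lon, lat = lat, date = date,
                              value = value),
         truth = list(mean_field = truth, hotspot_cell = hotspot_cell,
                      seed = seed))
  })
}

#' Generate a synthetic fine-resolution chlorophyll raster
#'
#' A smooth coastal gradient (high nearshore, low offshore, transitioning
#' around `coastal_lat`) times log-normal noise, at satellite-product
#' resolution (default 1/12 degree). `uniform_value` replaces the whole
#' field with a constant, which is the idempotence fixture for regridding.
#'
#' @param seed Integer seed.
#' @param grid A `grid_spec` (sets the raster's latitude extent).
#' @param fine_resolution Raster resolution in degrees; must be finer than
#'   the grid.
#' @param nearshore,offshore Mean concentrations (mg m^-3) at the coast and
#'   offshore.
#' @param coastal_lat Centre of the nearshore-offshore transition.
#' @param noise_sdlog Log-scale multiplicative noise; 0 disables.
#' @param uniform_value If non-`NULL`, emit a constant field of this value.
#' @return A [fine_raster()].
#' @export
gen_chl_raster <- function(seed = 1, grid = build_grid(),
                           fine_resolution = 1 / 12,
                           nearshore = 2, offshore = 0.15,
                           coastal_lat = -63, noise_sdlog = 0.3,
                           uniform_value = NULL) {
  stopifnot(fine_resolution < grid$lon_width,
            fine_resolution < grid$lat_width)
  lon <- seq(-180 + fine_resolution / 2, 180, by = fine_resolution)
  lat <- seq(grid$lat_south_limit + fine_resolution / 2,
             grid$lat_north_limit, by = fine_resolution)
  if (!is.null(uniform_value)) {
    return(fine_raster(lon, lat,
                       matrix(uniform_value, length(lat), length(lon))))
  }
  base_lat <- offshore + (nearshore - offshore) *
    stats::plogis((coastal_lat - lat) / 2)
  vals <- matrix(base_lat, length(lat), length(lon)) # constant along lon
  with_seed(seed, {
    if (noise_sdlog > 0) {
      vals <- vals * matrix(stats::rlnorm(length(vals), 0, noise_sdlog),
                            length(lat), length(lon))
    }
    fine_raster(lon, lat, vals)
  })
}

#' Generate a per-cell true trend field
#'
#' @param grid A `grid_spec`.
#' @param seed Integer seed.
#' @param magnitude Range of absolute gradients (units per year).
#' @param sign `"both"` (random sign, SST-like), `"negative"` (pH-like), or
#'   `"positive"`.
#' @return Matrix `n_rows x n_cols` of true gradients.
#' @export
gen_trend_field <- function(grid = build_grid(), seed = 1,
                            magnitude = c(0.003, 0.012),
                            sign = c("both", "negative", "positive")) {
  sign <- match.arg(sign)
  with_seed(seed, {
    n <- grid$n_rows * grid$n_cols
    mag <- stats::runif(n, magnitude[1], magnitude[2])
    s <- switch(sign,
                both = sample(c(-1, 1), n, replace = TRUE),
                negative = -1,
                positive = 1)
    matrix(mag * s, grid$n_rows, grid$n_cols)
  })
}

#' Generate synthetic environmental series (SST-like or pH-like)
#'
#' Per cell: `base + trend * t + amplitude * sin(2 pi month/12) + AR(1)
#' noise`, emitted daily (SST-like source products) or monthly (pH-like).
#' With `sigma = 0` the series is exactly linear-plus-seasonal, the
#' noiseless limit in which the five-step trend method must recover the
#' injected gradients exactly.
#'
#' @param grid A `grid_spec`.
#' @param trend_field Matrix of true gradients (units per year), e.g. from
#'   [gen_trend_field()].
#' @param seed Integer seed.
#' @param start_year,end_year Inclusive span of the series.
#' @param freq `"monthly"` or `"daily"`.
#' @param base Scalar or matrix base level.
#' @param amplitude Scalar or matrix seasonal amplitude.
#' @param phi AR(1) coefficient of the noise.
#' @param sigma AR(1) innovation standard deviation (0 = noiseless).
#' @return A [series_field()].
#' @export
gen_env_series <- function(grid = build_grid(), trend_field, seed = 1,
                           start_year = 1982, end_year = 2021,
                           freq = c("monthly", "daily"),
                           base = 0, amplitude = 1,
                           phi = 0.5, sigma = 0.05) {
  freq <- match.arg(freq)
  stopifnot(is.matrix(trend_field),
            nrow(trend_field) == grid$n_rows,
            ncol(trend_field) == grid$n_cols)
  if (!is.matrix(base)) base <- matrix(base, grid$n_rows, grid$n_cols)
  if (!is.matrix(amplitude)) {
    amplitude <- matrix(amplitude, grid$n_rows, grid$n_cols)
  }
  if (freq == "monthly") {
    n_t <- (end_year - start_year + 1L) * 12L
    t_years <- (seq_len(n_t) - 0.5) / 12
    season <- sin(2 * pi * (seq_len(n_t) - 0.5) / 12)
    dates <- NULL
  } else {
    dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
                 as.Date(sprintf("%d-12-31", end_year)), by = "day")
    n_t <- length(dates)
    t_years <- as.numeric(dates - dates[1]) / 365.25
    season <- sin(2 * pi * (as.integer(format(dates, "%j")) - 0.5) / 365.25)
  }
  vals <- array(NA_real_, dim = c(n_t, grid$n_rows, grid$n_cols))
  with_seed(seed, {
    for (row in seq_len(grid$n_rows)) {
      for (col in seq_len(grid$n_cols)) {
        noise <- if (sigma > 0) {
          as.numeric(stats::filter(stats::rnorm(n_t, 0, sigma), phi,
                                   method = "recursive"))
        } else 0
        vals[, row, col] <- base[row, col] +
          trend_field[row, col] * t_years +
          amplitude[row, col] * season + noise
      }
    }
  })
  if (freq == "monthly") {
    series_field(grid, vals, start_year = start_year, start_month = 1L)
  } else {
    series_field(grid, vals, dates = dates)
  }
}

#' Generate a complete synthetic input bundle
#'
#' Convenience wrapper drawing every pipeline input from one master seed
#' (sub-seeds are derived deterministically), with the engineered hotspot
#' region co-locating the facility cluster, traffic maximum, and krill
#' maximum.
#'
#' @param seed Master integer seed.
#' @param grid A `grid_spec`.
#' @param n_facilities,n_krill Catalogue and sample sizes.
#' @param env_years `c(start, end)` span of the environmental series.
#' @param chl_resolution Fine chlorophyll resolution, degrees.
#' @param sst_sigma,ph_sigma AR(1) innovation standard deviations of the two
#'   environmental series.
#' @param phi AR(1) coefficient shared by both.
#' @param neutral_abiotic Plant no abiotic spatial structure: zero trend
#'   fields and noiseless series, so every cell comes out insignificant and
#'   the abiotic rank layer is uniform. The engineered fixture co-locates
#'   only the traffic, facility, and biota maxima; a neutral abiotic field
#'   keeps that planted region the known answer of the end-to-end map
#'   instead of letting an unrelated random trend draw decide ties.
#' @return List with `facilities`, `ship_records`, `krill_samples`,
#'   `chl_raster`, `sst_field`, `ph_field`, `persons_aboard`, and `truth`.
#' @export
gen_input_bundle <- function(seed = 1, grid = build_grid(),
                             n_facilities = 112, n_krill = 2000,
                             env_years = c(1995, 2014),
                             chl_resolution = 1 / 4,
                             sst_sigma = 0.05, ph_sigma = 0.005,
                             phi = 0.5, neutral_abiotic = FALSE) {
  seeds <- seed * 7L + 0:6
  fac <- gen_facilities(n_facilities, seed = seeds[1], grid = grid)
  ships <- gen_ship_traffic(fac$facilities, grid = grid, seed = seeds[2])
  krill <- gen_krill_samples(n_krill, seed = seeds[3], grid = grid,
                             hotspot_cell = fac$truth$hotspot_cell)
  chl <- gen_chl_raster(seed = seeds[4], grid = grid,
                        fine_resolution = chl_resolution)
  if (neutral_abiotic) {
    sst_truth <- matrix(0, grid$n_rows, grid$n_cols)
    ph_truth <- matrix(0, grid$n_rows, grid$n_cols)
    sst_sigma <- 0
    ph_sigma <- 0
  } else {
    sst_truth <- gen_trend_field(grid, seed = seeds[5], sign = "both")
    ph_truth <- gen_trend_field(grid, seed = seeds[6],
                                magnitude = c(0.0005, 0.003),
                                sign = "negative")
  }
  sst <- gen_env_series(grid, sst_truth, seed = seeds[5] + 1000L,
                        start_year = env_years[1], end_year = env_years[2],
                        phi = phi, sigma = sst_sigma)
  ph <- gen_env_series(grid, ph_truth, seed = seeds[6] + 1000L,
                       start_year = env_years[1], end_year = env_years[2],
                       amplitude = 0.02, phi = phi, sigma = ph_sigma)
  list(facilities = fac$facilities,
       ship_records = ships,
       krill_samples = krill$samples,
       chl_raster = chl,
       sst_field = sst,
       ph_field = ph,
       persons_aboard = c(fishing = 40, tourist = 150, "cargo/supply" = 25,
                          research = 50, other = 20),
       truth = list(hotspot_cell = fac$truth$hotspot_cell,
                    krill_field = krill$truth$mean_field,
                    sst_trends = sst_truth, ph_trends = ph_truth,
                    seed = seed))
}
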