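#' Read a point-sample table (krill-style CSV)
#'
#' Expects columns `lon`, `lat`, `date`, `value`. Row-level problems
#' (unparseable coordinates or dates, negative values) are collected and
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_point_samples <- function(path) {
  df <- read_checked_csv(path, c("lon", "lat", "date", "value"))
  problems <- character(0)
  bad_coord <- which(is.na(df$lon) | is.na(df$lat) |
                     abs(df$lon) > 180 | abs(df$lat) > 90)
  if (length(bad_coord)) {
    problems <- c(problems, paste0("invalid coordinates at line(s) ",
                                   line_list(bad_coord)))
  }
  dates <- as.Date(as.character(df$date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    problems <- c(problems, paste0("unparseable dates at line(s) ",
                                   line_list(which(is.na(dates)))))
  }
  bad_val <- which(is.na(df$value) | df$value < 0)
  if (length(bad_val)) {
    problems <- c(problems, paste0("missing or negative values at line(s) ",
                                   line_list(bad_val)))
  }
  if (length(problems)) {
    stop("invalid point-sample file '", path, "': ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  df$date <- dates
  df
}

#' Read a facility catalogue (COMNAP-style CSV)
#'
#' Expects columns `name`, `lon`, `lat`, `facility_type`, `seasonality`,
#' `peak_population`.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_facilities <- function(path) {
  df <- read_checked_csv(path, c("name", "lon", "lat", "facility_type",
                                 "seasonality", "peak_population"))
  bad_season <- which(!df$seasonality %in% c("year-round", "seasonal"))
  if (length(bad_season)) {
    stop("invalid facility file '", path, "': unknown seasonality at line(s) ",
         line_list(bad_season), call. = FALSE)
  }
  bad_pop <- which(is.na(df$peak_population) | df$peak_population < 0)
  if (length(bad_pop)) {
    stop("invalid facility file '", path,
         "': missing or negative peak_population at line(s) ",
         line_list(bad_pop), call. = FALSE)
  }
  df
}

#' Read a ship-record table (AIS-derived CSV)
#'
#' Expects columns `vessel_id`, `vessel_type`, `year`, `days`, and either
#' `col`/`row` or `lon`/`lat`.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_ship_records <- function(path) {
  df <- read_checked_csv(path, c("vessel_id", "vessel_type", "year", "days"))
  if (!all(c("col", "row") %in% names(df)) &&
      !all(c("lon", "lat") %in% names(df))) {
    stop("invalid ship-record file '", path,
         "': need either col/row or lon/lat columns", call. = FALSE)
  }
  bad_days <- which(is.na(df$days) | df$days < 0)
  if (length(bad_days)) {
    stop("invalid ship-record file '", path,
         "': missing or negative days at line(s) ", line_list(bad_days),
         call. = FALSE)
  }
  df
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

# data line numbers in the file (1 header line)
line_list <- function(rows, max_shown = 5) {
  shown <- utils::head(rows + 1L, max_shown)
  paste0(paste(shown, collapse = ", "),
         if (length(rows) > max_shown) sprintf(" (+%d more)", length(rows) - max_shown))
}

#' Write / read gridded layers as long-format CSV
#'
#' Lossless tabular serialisation of a `value_layer` (`col`, `row`, `value`,
#' `n_obs`; missing cells have empty `value` and `n_obs` 0).
#'
#' @param layer A `value_layer`.
#' @param path Output CSV path.
#' @param grid A `grid_spec` matching the written layer.
#' @return `write_value_layer`: the path, invisibly. `read_value_layer`: the
#'   reconstructed `value_layer`.
#' @export
write_value_layer <- function(layer, path) {
  stopifnot(inherits(layer, "value_layer"))
  df <- layer_to_df(layer)
  utils::write.csv(df[, c("col", "row", "value", "n_obs")], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_value_layer
#' @export
read_value_layer <- function(path, grid) {
  df <- read_checked_csv(path, c("col", "row", "value", "n_obs"))
  out <- value_layer(grid, NA_real_,
                     n_obs = matrix(0L, grid$n_rows, grid$n_cols))
  mi <- cell_mat_index(df$col, df$row, grid)
  out$values[mi] <- df$value
  out$n_obs[mi] <- as.integer(df$n_obs)
  out
}

#' Export a gridded layer or grid as GeoJSON
#'
#' One polygon feature per cell with `col`, `row`, `area_km2`, and (for
#' layers) the cell value/score properties. Plain lon/lat (CRS84)
#' coordinates; cells are rectangles in lon/lat space.
#'
#' @param x A `grid_spec`, `value_layer`, `rank_layer`, or `risk_map`.
#' @param path Output `.geojson` path.
#' @param drop_missing For layers, omit cells without data?
#' @return The path, invisibly.
#' @export
write_geojson <- function(x, path, drop_missing = TRUE) {
  if (is_grid_spec(x)) {
    df <- grid_cells(x)
    grid <- x
    value_name <- NULL
  } else {
    grid <- x$grid
    df <- layer_to_df(x, drop_missing = drop_missing)
    value_name <- if (inherits(x, "risk_map")) "score"
                  else if (inherits(x, "rank_layer")) "rank" else "value"
  }
  b <- cell_bounds(df$col, df$row, grid)
  features <- lapply(seq_len(nrow(df)), function(i) {
    props <- list(col = df$col[i], row = df$row[i],
                  area_km2 = df$area_km2[i])
    if (!is.null(value_name)) props[[value_name]] <- df$value[i]
    ring <- list(c(b$lon_min[i], b$lat_min[i]),
                 c(b$lon_max[i], b$lat_min[i]),
                 c(b$lon_max[i], b$lat_max[i]),
                 c(b$lon_min[i], b$lat_max[i]),
                 c(b$lon_min[i], b$lat_min[i]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Default pipeline configuration
#'
#' The resolved configuration drives [run_pipeline()] and is embedded in the
#' run report. Any subset can be overridden via `...` or a YAML file
#' ([read_config()]).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    grid = list(lon_width = 9, lat_width = 3, lat_north_limit = -45,
                lat_south_limit = -90, earth_radius_km = 6371.0072),
    month_filter = 1:3,
    climatology_reference = c(1993L, 2014L),
    alpha = 0.05,
    trend_fit_on = "trend",
    trim_months = 48L,
    outlier_quantiles = c(0.01, 0.99),
    facility_density_method = "inverse_square",
    facility_seasonal_weighting = FALSE,
    persons_aboard = c(fishing = 40, tourist = 150, "cargo/supply" = 25,
                       research = 50, other = 20),
    ship_mask_lat = -60,
    hotspot_threshold = 4,
    seed = 1L,
    synthetic = list(n_facilities = 112, n_krill = 2000,
                     env_years = c(1995L, 2014L), chl_resolution = 1 / 4,
                     sst_sigma = 0.05, ph_sigma = 0.005, phi = 0.5,
                     neutral_abiotic = FALSE),
    inputs = NULL, # list of file paths; NULL = generate synthetically
    out_dir = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return Resolved configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]) && nm != "inputs") {
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (!is.null(cfg$persons_aboard)) {
    cfg$persons_aboard <- unlist(cfg$persons_aboard)
  }
  cfg
}

#' Read and validate the configured input bundle
#'
#' With `config$inputs` set, reads and schema-validates the CSV inputs (krill
#' samples, facilities, ship records) from disk; otherwise generates the
#' full synthetic bundle from `config$seed`. Gridded chlorophyll and
#' environmental series are always generated synthetically unless provided
#' in-memory, as their source products are external.
#'
#' @param config Configuration list (see [default_config()]).
#' @return Input bundle list (see [gen_input_bundle()]).
#' @export
read_inputs <- function(config = default_config()) {
  grid <- do.call(build_grid, config$grid)
  syn <- config$synthetic
  bundle <- gen_input_bundle(seed = config$seed, grid = grid,
                             n_facilities = syn$n_facilities,
                             n_krill = syn$n_krill,
                             env_years = syn$env_years,
                             chl_resolution = syn$chl_resolution,
                             sst_sigma = syn$sst_sigma,
                             ph_sigma = syn$ph_sigma, phi = syn$phi,
                             neutral_abiotic = isTRUE(syn$neutral_abiotic))
  if (!is.null(config$inputs)) {
    paths <- config$inputs
    if (!is.null(paths$krill_samples)) {
      bundle$krill_samples <- read_point_samples(paths$krill_samples)
    }
    if (!is.null(paths$facilities)) {
      bundle$facilities <- read_facilities(paths$facilities)
      bundle$truth <- NULL
    }
    if (!is.null(paths$ship_records)) {
      bundle$ship_records <- read_ship_records(paths$ship_records)
    }
  }
  bundle$persons_aboard <- config$persons_aboard
  bundle$grid <- grid
  bundle
}

#' Run the full risk-mapping pipeline
#'
#' Executes every stage on an input bundle: grids the krill samples and
#' chlorophyll raster (geometric mean with zeros, January-March), fits
#' per-cell SST and pH trends with the five-step method, converts ship
#' records and facilities to person-day intensity layers, ranks all six
#' layers on the 1-5 scale, and composes risk maps A-F. With `out_dir` set,
#' writes each map as GeoJSON, each continuous layer as CSV, and a YAML run
#' report containing the resolved configuration, fitted scales, and input
#' checksums. Deterministic given the configuration and seed.
#'
#' @param config Configuration list (see [default_config()]).
#' @param bundle Optional pre-built input bundle; default [read_inputs()].
#' @return Invisibly, a list with `maps` (A-F), `ranks`, `layers`,
#'   `trends`, `hotspots`, the `grid`, and the `bundle` used.
#' @export
run_pipeline <- function(config = default_config(), bundle = NULL) {
  t0 <- Sys.time()
  stage <- function(name) message(sprintf("[sorisk] %-12s %+.1fs", name,
                                          as.numeric(Sys.time() - t0, units = "secs")))
  if (is.null(bundle)) bundle <- read_inputs(config)
  grid <- bundle$grid %||% do.call(build_grid, config$grid)

  stage("biota")
  krill_layer <- grid_point_samples(bundle$krill_samples, grid,
                                    month_filter = config$month_filter)
  chl_layer <- regrid_raster_geomean(bundle$chl_raster, grid)
  krill_layer$name <- "krill"
  chl_layer$name <- "chlorophyll"

  stage("trends")
  sst_trends <- trend_map(bundle$sst_field,
                          reference = config$climatology_reference,
                          alpha = config$alpha,
                          fit_on = config$trend_fit_on,
                          trim_months = config$trim_months)
  ph_trends <- trend_map(bundle$ph_field,
                         reference = config$climatology_reference,
                         alpha = config$alpha,
                         fit_on = config$trend_fit_on,
                         trim_months = config$trim_months)

  stage("human")
  ships <- ship_person_days(bundle$ship_records, bundle$persons_aboard, grid)
  fac_density <- effective_population_density(
    bundle$facilities, grid,
    method = config$facility_density_method,
    seasonal_weighting = config$facility_seasonal_weighting)

  stage("rank")
  oq <- config$outlier_quantiles
  rank_of <- function(layer, transform) {
    apply_ranks(layer, fit_rank_scale(layer, transform = transform,
                                      outlier_quantiles = oq))
  }
  ranks <- list(
    krill = rank_of(krill_layer, "log"),
    chl = rank_of(chl_layer, "log"),
    sst = rank_trend_layer(sst_trends, "warming", outlier_quantiles = oq),
    ph = rank_trend_layer(ph_trends, "acidification", outlier_quantiles = oq),
    ship = rank_of(ships$total, "log"),
    facility = rank_of(fac_density, "log")
  )

  stage("compose")
  maps <- build_all_maps(ranks$krill, ranks$chl, ranks$sst, ranks$ph,
                         ranks$ship, ranks$facility,
                         mask_lat = config$ship_mask_lat)
  hotspots <- hotspot_cells(maps$F, config$hotspot_threshold)

  result <- list(maps = maps, ranks = ranks,
                 layers = list(krill = krill_layer, chl = chl_layer,
                               ship_total = ships$total,
                               facility_density = fac_density),
                 trends = list(sst = sst_trends, ph = ph_trends),
                 hotspots = hotspots, grid = grid, bundle = bundle,
                 config = config)
  if (!is.null(config$out_dir)) {
    stage("write")
    write_pipeline_outputs(result, config$out_dir)
  }
  stage("done")
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  ok <- FALSE
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  on.exit(if (!ok) unlink(out_dir, recursive = TRUE))
  for (nm in names(result$maps)) {
    write_geojson(result$maps[[nm]],
                  file.path(out_dir, paste0("map_", nm, ".geojson")))
  }
  for (nm in names(result$layers)) {
    write_value_layer(result$layers[[nm]],
                      file.path(out_dir, paste0("layer_", nm, ".csv")))
  }
  utils::write.csv(result$hotspots, file.path(out_dir, "hotspots.csv"),
                   row.names = FALSE)
  scales <- lapply(result$ranks, function(r) {
    if (is.null(r$scale)) return(NULL)
    list(transform = r$scale$transform,
         thresholds = as.numeric(r$scale$thresholds),
         outlier_bounds = as.numeric(r$scale$outlier_bounds),
         zero_rule = r$scale$zero_rule)
  })
  csvs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  report <- list(
    package = "sorisk",
    version = as.character(utils::packageVersion("sorisk")),
    config = serialisable(result$config),
    scales = scales,
    trend_failures = list(sst = result$trends$sst$failures,
                          ph = result$trends$ph$failures),
    output_checksums = as.list(tools::md5sum(csvs))
  )
  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  ok <- TRUE
  invisible(out_dir)
}

serialisable <- function(x) {
  if (is.list(x)) return(lapply(x, serialisable))
  if (is.function(x)) return(NULL)
  x
}
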