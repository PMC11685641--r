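#' Annual person-days of a facility
#'
#' Converts facility population to the pipeline's common human-presence
#' currency: year-round facilities are assumed to operate at peak population
#' `p` all year (365 p person-days per year) while seasonal facilities
#' operate for six months (182.5 p).
#'
#' @param facility Data frame with columns `seasonality` (`"year-round"` or
#'   `"seasonal"`) and `peak_population`, or a character vector of
#'   seasonalities with `peak_population` supplied separately.
#' @param peak_population Populations when `facility` is a character vector.
#' @return Numeric vector of person-days per year.
#' @examples
#' annual_person_days("year-round", 1) # 365
#' annual_person_days("seasonal", 1)   # 182.5
#' @export
annual_person_days <- function(facility, peak_population = NULL) {
  if (is.data.frame(facility)) {
    seasonality <- facility$seasonality
    peak_population <- facility$peak_population
  } else {
    seasonality <- facility
  }
  stopifnot(length(seasonality) == length(peak_population),
            all(peak_population >= 0))
  days <- c("year-round" = 365, "seasonal" = 182.5)[seasonality]
  if (anyNA(days)) {
    stop("unknown seasonality: ",
         paste(unique(seasonality[is.na(days)]), collapse = ", "),
         " (expected 'year-round' or 'seasonal')", call. = FALSE)
  }
  unname(days * peak_population)
}

#' Seasonally weighted effective population
#'
#' Annualised population for the density proxy: year-round facilities
#' contribute their peak population `p`, seasonal ones `p/2` (the 182.5/365
#' person-day ratio).
#'
#' @inheritParams annual_person_days
#' @return Numeric vector of effective people.
#' @export
seasonally_weighted_population <- function(facility, peak_population = NULL) {
  annual_person_days(facility, peak_population) / 365
}

#' Ship traffic person-day layers
#'
#' Converts per-vessel ship-day records into person-day intensity: ship time
#' per cell is multiplied by the typical persons on board the vessel's type,
#' summed within each of the five vessel-type groups and year, then averaged
#' across years. Summing the five type layers gives the total annual
#' ship-traffic layer.
#'
#' @param records Data frame with columns `vessel_id`, `vessel_type`, `year`,
#'   `days`, and either 0-based `col`/`row` cell indices or `lon`/`lat`
#'   coordinates.
#' @param persons Named numeric vector mapping each vessel type appearing in
#'   `records` to typical persons on board.
#' @param grid A `grid_spec`.
#' @param years Years over which to average; default the distinct years in
#'   `records` (a cell-year with no records counts as zero ship time).
#' @return List with `by_type` (named list of `value_layer`, person-days
#'   yr^-1) and `total` (their sum).
#' @export
ship_person_days <- function(records, persons, grid, years = NULL) {
  stopifnot(is.data.frame(records),
            all(c("vessel_id", "vessel_type", "year", "days") %in% names(records)),
            all(records$days >= 0))
  types <- unique(as.character(records$vessel_type))
  missing_types <- setdiff(types, names(persons))
  if (length(missing_types) > 0) {
    stop("no persons-aboard value configured for vessel type(s): ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  if (is.null(years)) years <- unique(records$year)
  n_years <- length(unique(years))
  if (!all(c("col", "row") %in% names(records))) {
    stopifnot(all(c("lon", "lat") %in% names(records)))
    idx <- assign_cell(records$lon, records$lat, grid)
    records$col <- idx$col
    records$row <- idx$row
  }
  records <- records[!is.na(records$col) & records$year %in% years, , drop = FALSE]
  empty <- function() matrix(0, grid$n_rows, grid$n_cols)
  by_type <- list()
  for (ty in sort(types)) {
    sub <- records[records$vessel_type == ty, , drop = FALSE]
    vals <- empty()
    if (nrow(sub) > 0) {
      pd <- sub$days * persons[[ty]]
      key <- sub$row * grid$n_cols + sub$col
      agg <- tapply(pd, key, sum) / n_years # interannual mean incl. zero years
      kcol <- as.integer(names(agg)) %% grid$n_cols
      krow <- as.integer(names(agg)) %/% grid$n_cols
      vals[cell_mat_index(kcol, krow, grid)] <- as.numeric(agg)
    }
    by_type[[ty]] <- value_layer(grid, vals, name = paste0("ship_", ty))
  }
  total <- Reduce(`+`, lapply(by_type, function(l) l$values))
  list(by_type = by_type,
       total = value_layer(grid, total, name = "ship_total"))
}

#' Effective population density of terrestrial facilities
#'
#' The facility emission proxy, in people per 10,000 km^2. For a grid cell
#' containing facilities, the density is the total population housed in them
#' divided by the cell area. For every other cell, each facility's population
#' is smoothed uniformly over the disc whose radius is the great-circle
#' distance `d` from the facility to the cell centroid, contributing
#' `p / (pi d^2)`; contributions are summed over all facilities. This models
#' effective population as an inverse square of distance, representing
#' uniform, undirected dispersion of emissions.
#'
#' `method = "areal_product"` is an alternative reading in which the disc
#' density is additionally multiplied by the ratio of cell area to disc area
#' (an inverse-fourth-power law); it is provided for comparison only.
#'
#' @param facilities Data frame with columns `lon`, `lat`, `peak_population`,
#'   and (if `seasonal_weighting`) `seasonality`.
#' @param grid A `grid_spec`.
#' @param method `"inverse_square"` (default) or `"areal_product"`.
#' @param seasonal_weighting Use [seasonally_weighted_population()] instead
#'   of raw peak population?
#' @return A `value_layer` of people per 10,000 km^2 (all cells >= 0).
#' @export
effective_population_density <- function(facilities, grid,
                                         method = c("inverse_square", "areal_product"),
                                         seasonal_weighting = FALSE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(facilities))
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  if (nrow(facilities) > 0) {
    stopifnot(all(c("lon", "lat", "peak_population") %in% names(facilities)))
    pop <- if (seasonal_weighting) {
      seasonally_weighted_population(facilities)
    } else {
      facilities$peak_population
    }
    cells <- grid_cells(grid)
    fcell <- assign_cell(facilities$lon, facilities$lat, grid)
    fkey <- fcell$row * grid$n_cols + fcell$col
    ckey <- cells$row * grid$n_cols + cells$col
    # great-circle distances facility x cell-centroid: haversine central
    # angle (geosphere default radius 6378137 m) rescaled to the grid's
    # authalic sphere, km
    dmat <- geosphere::distm(cbind(facilities$lon, facilities$lat),
                             cbind(cells$lon, cells$lat),
                             fun = geosphere::distHaversine) /
      6378137 * grid$earth_radius_km
    for (j in seq_len(nrow(cells))) {
      inside <- !is.na(fkey) & fkey == ckey[j]
      if (any(inside)) {
        dens <- sum(pop[inside]) / cells$area_km2[j]
      } else {
        d <- dmat[, j]
        contrib <- pop / (pi * d^2)
        if (method == "areal_product") {
          contrib <- contrib * cells$area_km2[j] / (pi * d^2)
        }
        dens <- sum(contrib)
      }
      vals[cells$row[j] + 1L, cells$col[j] + 1L] <- dens * 1e4
    }
  }
  value_layer(grid, vals, name = "facility_density")
}
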