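#' Mean-rank composition
#'
#' Composes rank layers (or already-composed risk maps) into a continuous
#' score in `[1, 5]` by the per-cell arithmetic mean of the contributing
#' values. A cell missing in some inputs uses the mean of those present —
#' where krill data are lacking, the biota score is defined entirely by the
#' chlorophyll — and is missing only when absent from every input.
#'
#' @param layers List of `rank_layer` / `risk_map` objects sharing one grid.
#' @param name Optional map name.
#' @return An object of class `risk_map`: list with the `grid`, a `scores`
#'   matrix in `[1, 5]`, and `provenance` (contributing layer names).
#' @export
mean_rank <- function(layers, name = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1)
  grid <- layers[[1]]$grid
  mats <- lapply(layers, function(l) {
    if (!same_grid(l$grid, grid)) {
      stop("all layers must share the same grid", call. = FALSE)
    }
    if (inherits(l, "risk_map")) l$scores
    else if (inherits(l, "rank_layer")) l$ranks
    else stop("inputs must be rank_layer or risk_map objects", call. = FALSE)
  })
  arr <- array(unlist(mats), dim = c(grid$n_rows, grid$n_cols, length(mats)))
  n_present <- apply(!is.na(arr), c(1, 2), sum)
  total <- apply(arr, c(1, 2), function(x) sum(x, na.rm = TRUE))
  scores <- ifelse(n_present > 0, total / n_present, NA_real_)
  prov <- unlist(lapply(layers, function(l) {
    if (inherits(l, "risk_map")) l$provenance else l$name %||% "unnamed"
  }))
  structure(list(grid = grid, scores = scores, provenance = prov,
                 name = name),
            class = "risk_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.risk_map <- function(x, ...) {
  s <- x$scores
  cat(sprintf("<risk_map%s> %d scored cells, range [%.3g, %.3g]; from: %s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              sum(!is.na(s)),
              if (any(!is.na(s))) min(s, na.rm = TRUE) else NA,
              if (any(!is.na(s))) max(s, na.rm = TRUE) else NA,
              paste(x$provenance, collapse = ", ")))
  invisible(x)
}

#' Mask a map or layer to cells south of a latitude
#'
#' Cells whose centroid lies at or north of `lat_limit` become missing. Used
#' for the human-activity maps, whose ship-traffic data stop at 60 degrees S.
#'
#' @param map A `risk_map` or `rank_layer`.
#' @param lat_limit Latitude in degrees; default -60.
#' @return Object of the same class with northern cells set to missing.
#' @export
mask_south_of <- function(map, lat_limit = -60) {
  grid <- map$grid
  rows <- seq_len(grid$n_rows) - 1L
  cen_lat <- grid$lat_south_limit + (rows + 0.5) * grid$lat_width
  masked_rows <- which(cen_lat >= lat_limit)
  field <- if (inherits(map, "risk_map")) "scores" else "ranks"
  map[[field]][masked_rows, ] <- NA
  map
}

#' Build the six risk maps
#'
#' Composes the six ranked input layers into the baseline, interaction, and
#' combined maps:
#' \describe{
#'   \item{A}{biota prevalence = mean rank of krill and chlorophyll}
#'   \item{C}{abiotic stress = mean rank of SST and pH trends}
#'   \item{E}{human activity = mean rank of ship traffic and facilities,
#'     restricted to south of 60 degrees S (no ship data further north)}
#'   \item{B}{emissions x biota interaction = mean of E and A}
#'   \item{D}{emissions x abiotic interaction = mean of E and C}
#'   \item{F}{combined microplastic-hotspot map = mean of B and D}
#' }
#' The latitudinal mask on E propagates to B, D, and F; A and C keep their
#' full extent.
#'
#' @param krill,chl,sst,ph,ship,facility `rank_layer` objects on one grid.
#' @param mask_lat Northern limit for the human-activity maps (`NULL`
#'   disables the mask).
#' @return Named list of six `risk_map` objects `A`-`F`.
#' @export
build_all_maps <- function(krill, chl, sst, ph, ship, facility,
                           mask_lat = -60) {
  A <- mean_rank(list(krill, chl), name = "A_biota")
  C <- mean_rank(list(sst, ph), name = "C_abiotic")
  E <- mean_rank(list(ship, facility), name = "E_human")
  if (!is.null(mask_lat)) E <- mask_south_of(E, mask_lat)
  B <- mean_rank(list(E, A), name = "B_human_x_biota")
  D <- mean_rank(list(E, C), name = "D_human_x_abiotic")
  FF <- mean_rank(list(B, D), name = "F_combined")
  if (!is.null(mask_lat)) {
    # the mask on E propagates to everything downstream of it
    B <- mask_south_of(B, mask_lat)
    D <- mask_south_of(D, mask_lat)
    FF <- mask_south_of(FF, mask_lat)
  }
  list(A = A, B = B, C = C, D = D, E = E, F = FF)
}

#' Cells at or above a hotspot threshold
#'
#' @param map A `risk_map`.
#' @param threshold Score threshold in `[1, 5]`.
#' @return Data frame `col`, `row`, `score`, sorted by descending score.
#' @export
hotspot_cells <- function(map, threshold) {
  stopifnot(inherits(map, "risk_map"), threshold >= 1, threshold <= 5)
  df <- layer_to_df(map, drop_missing = TRUE)
  df <- df[df$value >= threshold, c("col", "row", "value")]
  names(df)[3] <- "score"
  df <- df[order(-df$score), , drop = FALSE]
  rownames(df) <- NULL
  df
}
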