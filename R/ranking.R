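#' Discrete 1-5 ranking scales
#'
#' Layers measured in incommensurable units are made comparable by grading
#' each cell on a discrete scale from 1 (least concern) to 5 (greatest).
#' Skewed layers are first transformed toward normality (log for abundances
#' and person-day intensities, square root for positive temperature trends),
#' zeros and outlying values are omitted, and four threshold values are set
#' at evenly spaced intervals across the retained transformed range, i.e. at
#' the interior points of a five-way equipartition, so each rank spans an
#' equal transformed interval.
#'
#' @param values Numeric values to fit on (a vector or a `value_layer`);
#'   `NA` ignored.
#' @param transform One of `"identity"`, `"log"`, `"sqrt"`, `"negate"`.
#' @param outlier_quantiles Length-2 probabilities clipping the transformed
#'   nonzero data (default 1st/99th percentile); `NULL` disables clipping.
#' @param zero_rule Omit zeros when fitting (they are later forced to rank 1)?
#' @param layer Optional layer name used in error messages.
#' @return An object of class `rank_scale`: list with `transform`,
#'   `thresholds` (4 ascending values on the transformed scale),
#'   `outlier_bounds`, and `zero_rule`.
#' @export
fit_rank_scale <- function(values, transform = "identity",
                           outlier_quantiles = c(0.01, 0.99),
                           zero_rule = TRUE, layer = NULL) {
  if (inherits(values, "value_layer")) {
    if (is.null(layer)) layer <- values$name
    values <- values$values
  }
  lab <- if (is.null(layer)) "layer" else paste0("layer '", layer, "'")
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  if (zero_rule) v <- v[v != 0]
  tv <- rank_transform(v, transform)
  tv <- tv[is.finite(tv)]
  if (is.null(outlier_quantiles)) {
    bounds <- c(-Inf, Inf)
  } else {
    stopifnot(length(outlier_quantiles) == 2,
              outlier_quantiles[1] < outlier_quantiles[2])
    bounds <- unname(stats::quantile(tv, outlier_quantiles, names = FALSE))
  }
  retained <- tv[tv >= bounds[1] & tv <= bounds[2]]
  if (length(unique(retained)) < 2) {
    stop("cannot fit a ranking scale for ", lab,
         ": fewer than 2 distinct values after omitting zeros and outliers",
         call. = FALSE)
  }
  lo <- min(retained)
  hi <- max(retained)
  structure(list(transform = transform,
                 thresholds = lo + (1:4) * (hi - lo) / 5,
                 outlier_bounds = bounds,
                 zero_rule = zero_rule,
                 range = c(lo, hi)),
            class = "rank_scale")
}

rank_transform <- function(x, transform) {
  switch(transform,
         identity = x,
         log = {
           if (any(x < 0, na.rm = TRUE)) {
             stop("negative value under log transform", call. = FALSE)
           }
           log(x)
         },
         sqrt = {
           if (any(x < 0, na.rm = TRUE)) {
             stop("negative value under sqrt transform", call. = FALSE)
           }
           sqrt(x)
         },
         negate = -x,
         stop("unknown transform '", transform, "'", call. = FALSE))
}

#' @export
print.rank_scale <- function(x, ...) {
  cat(sprintf("<rank_scale> transform %s, thresholds %s\n", x$transform,
              paste(signif(x$thresholds, 5), collapse = ", ")))
  invisible(x)
}

#' Apply a fitted ranking scale to a layer
#'
#' Cells take rank `1 + #(thresholds <= transformed value)`; a value exactly
#' on a threshold takes the higher rank (half-open bins, matching the grid
#' convention). Zeros are assigned rank 1 when the scale's zero rule is set;
#' values clipped as low/high outliers take rank 1/5; missing cells stay
#' missing.
#'
#' @param layer A `value_layer` (or bare numeric vector/matrix).
#' @param scale A [fit_rank_scale()] result.
#' @return A `rank_layer` (per-cell integers 1-5 or `NA`, carrying `scale`)
#'   when given a layer, else an integer vector.
#' @export
apply_ranks <- function(layer, scale) {
  stopifnot(inherits(scale, "rank_scale"))
  is_layer <- inherits(layer, "value_layer")
  v <- if (is_layer) layer$values else layer
  r <- rank_values(as.numeric(v), scale)
  if (!is_layer) {
    if (is.matrix(v)) r <- matrix(r, nrow(v), ncol(v))
    return(r)
  }
  structure(list(grid = layer$grid,
                 ranks = matrix(r, nrow(v), ncol(v)),
                 scale = scale, name = layer$name),
            class = "rank_layer")
}

rank_values <- function(v, scale) {
  out <- rep(NA_integer_, length(v))
  ok <- !is.na(v)
  zero <- ok & scale$zero_rule & v == 0
  out[zero] <- 1L
  rest <- ok & !zero
  if (any(rest)) {
    tv <- rank_transform(v[rest], scale$transform)
    r <- 1L + vapply(tv, function(x) sum(scale$thresholds <= x), integer(1))
    r[tv < scale$outlier_bounds[1]] <- 1L
    r[tv > scale$outlier_bounds[2]] <- 5L
    r <- pmin(pmax(r, 1L), 5L)
    out[rest] <- r
  }
  out
}

#' @export
print.rank_layer <- function(x, ...) {
  cat(sprintf("<rank_layer%s> %d ranked cells; counts: %s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              sum(!is.na(x$ranks)),
              paste(table(factor(x$ranks, levels = 1:5)), collapse = "/")))
  invisible(x)
}

#' Rank a trend field by magnitude of change
#'
#' Ranks abiotic-stress layers from per-cell linear trends. For `"warming"`
#' only statistically significant positive gradients are graded, on a square
#' root scale (positive sea surface temperature trends are right-skewed);
#' insignificant or negative cells are assumed low risk and take rank 1.
#' For `"acidification"` the magnitudes of significant negative (pH decline)
#' gradients are graded on the identity scale; positive or insignificant
#' cells take rank 1. Cells with no fitted trend stay missing.
#'
#' If every eligible gradient is identical (degenerate range), eligible cells
#' take rank 5 as the layer maximum.
#'
#' @param trends A [trend_map()] result (`trend_field`).
#' @param direction `"warming"` or `"acidification"`.
#' @param outlier_quantiles Passed to [fit_rank_scale()].
#' @return A `rank_layer`.
#' @export
rank_trend_layer <- function(trends, direction = c("warming", "acidification"),
                             outlier_quantiles = c(0.01, 0.99)) {
  stopifnot(inherits(trends, "trend_field"))
  direction <- match.arg(direction)
  grad <- trends$gradient
  sig <- trends$significant
  sig[is.na(sig)] <- FALSE
  if (direction == "warming") {
    eligible <- !is.na(grad) & sig & grad > 0
    mag <- grad
    transform <- "sqrt"
    name <- "sst_trend"
  } else {
    eligible <- !is.na(grad) & sig & grad < 0
    mag <- -grad
    transform <- "identity"
    name <- "ph_trend"
  }
  ranks <- matrix(NA_integer_, nrow(grad), ncol(grad))
  ranks[!is.na(grad)] <- 1L
  scale <- NULL
  if (any(eligible)) {
    ev <- mag[eligible]
    if (length(unique(ev)) < 2) {
      ranks[eligible] <- 5L
    } else {
      scale <- fit_rank_scale(ev, transform = transform,
                              outlier_quantiles = outlier_quantiles,
                              zero_rule = FALSE, layer = name)
      ranks[eligible] <- rank_values(ev, scale)
    }
  }
  structure(list(grid = trends$grid, ranks = ranks, scale = scale,
                 name = name),
            class = "rank_layer")
}
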