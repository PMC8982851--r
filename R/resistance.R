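# Suitability -> landscape resistance. The linear transform anchors the
# cost scale: crossing a 1-km cell of suitability 1.0 costs 1 cost-weighted
# km, and one of suitability 0.01 costs 100. The non-linear variant squares
# the linear cost to express steeper avoidance of poor habitat.

#' Construct a resistance surface
#'
#' Wraps a raster of per-cell traversal costs (cost-weighted km per km of
#' travel). Most users derive resistance from suitability via
#' [linear_resistance()] or [nonlinear_resistance()]; this constructor
#' admits externally supplied cost rasters. Costs must be positive on valid
#' cells; nodata cells are treated as untraversable by the connectivity
#' stage.
#'
#' @param grid a `raster_grid` of traversal costs.
#' @param scaling provenance tag: `"linear"`, `"nonlinear"` or `"custom"`.
#' @param source_species species (or `"stacked"`) the surface derives from.
#' @return an object of class `resistance_surface`.
#' @export
resistance_surface <- function(grid, scaling = "custom",
                               source_species = "unknown") {
  v <- grid$values[valid_mask(grid)]
  if (length(v) > 0 && min(v) <= 0) {
    stop("resistance values must be positive on valid cells")
  }
  structure(list(grid = grid, scaling = scaling,
                 source_species = source_species),
            class = "resistance_surface")
}

#' @export
print.resistance_surface <- function(x, ...) {
  cat(sprintf("resistance_surface: %s scaling, species %s\n",
              x$scaling, x$source_species))
  print(x$grid)
  invisible(x)
}

check_unit_interval <- function(map) {
  v <- map$grid$values[valid_mask(map$grid)]
  if (length(v) > 0 && (min(v) < -1e-9 || max(v) > 1 + 1e-9)) {
    stop("suitability values must lie in [0, 1]; rescale stacked maps with normalize_stacked() first")
  }
}

#' Linearly scaled resistance surface
#'
#' Per-cell traversal cost `(1 - HS) * 100 + 1` (cost-weighted km per km of
#' travel), so suitability 1 costs 1 and suitability 0.01 costs 100. Cost is
#' strictly decreasing in suitability and bounded in \[1, 101\]. Nodata
#' cells stay nodata (treated as untraversable downstream).
#'
#' @param hs a `suitability_map` with values in \[0, 1\] (normalise stacked
#'   maps first, see [normalize_stacked()]).
#' @return a `resistance_surface` with `scaling = "linear"`.
#' @export
linear_resistance <- function(hs) {
  check_unit_interval(hs)
  g <- hs$grid
  ok <- valid_mask(g)
  g$values[ok] <- (1 - pmin(1, pmax(0, g$values[ok]))) * 100 + 1
  g$values[!ok] <- 0
  resistance_surface(g, "linear", hs$species_label)
}

#' Non-linearly scaled resistance surface
#'
#' The square of the linear cost: `((1 - HS) * 100 + 1)^2`, in
#' \[1, 10201\]. Preserves the suitability ranking of cells (any strictly
#' increasing transform of the linear cost would) while penalising poor
#' habitat much more steeply.
#'
#' @inheritParams linear_resistance
#' @return a `resistance_surface` with `scaling = "nonlinear"`.
#' @export
nonlinear_resistance <- function(hs) {
  lin <- linear_resistance(hs)
  g <- lin$grid
  ok <- valid_mask(g)
  g$values[ok] <- g$values[ok]^2
  resistance_surface(g, "nonlinear", hs$species_label)
}

#' Rescale a stacked suitability map to the unit interval
#'
#' A stacked map over S species lives in \[0, S\]; dividing by S returns it
#' to \[0, 1\] so the resistance transforms keep their 1-to-101 cost
#' anchors.
#'
#' @param stacked a `suitability_map` with values in \[0, n_species\].
#' @param n_species number of species summed into the map; defaults to the
#'   map's own record.
#' @return a `suitability_map` with values in \[0, 1\] and the same label.
#' @export
normalize_stacked <- function(stacked, n_species = stacked$n_species) {
  v <- stacked$grid$values[valid_mask(stacked$grid)]
  if (length(v) > 0 && (min(v) < -1e-9 || max(v) > n_species + 1e-9)) {
    stop(sprintf("stacked values must lie in [0, %d]", n_species))
  }
  g <- stacked$grid
  g$values <- g$values / n_species
  suitability_map(g, species_label = stacked$species_label, n_species = 1)
}
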