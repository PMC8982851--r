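#' Raster grid objects
#'
#' A `raster_grid` is the common spatial currency of the package: a 2-D matrix
#' of cell values on a regular square lattice, together with the map-unit
#' origin (lower-left corner), cell size and a nodata mask.
#'
#' Conventions, stated once and used everywhere: the value matrix is indexed
#' row-major from the top-left, so row 1 is the northern edge; x increases
#' east with column index, y increases north (i.e. decreases with row index).
#' Point coordinates refer to cell centres.
#'
#' @param values numeric matrix of cell values (row 1 = north).
#' @param origin length-2 numeric, map coordinates (m) of the lower-left
#'   corner of the grid (ESRI `xllcorner`/`yllcorner`).
#' @param cell_size cell edge length in metres; cells are square.
#' @param nodata logical matrix marking cells outside the study area, or
#'   `NULL` for none.
#' @param crs_label free-text label for the coordinate system.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell_size = 1000,
                        nodata = NULL, crs_label = "local-equal-area") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (cell_size <= 0) stop("cell_size must be positive")
  if (is.null(nodata)) {
    nodata <- matrix(FALSE, nrow(values), ncol(values))
  }
  if (!identical(dim(nodata), dim(values))) {
    stop("nodata mask dimensions must match values")
  }
  if (any(!is.finite(values[!nodata]))) {
    stop("values must be finite wherever nodata is FALSE")
  }
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), nodata = nodata,
         crs_label = crs_label),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!x$nodata]
  cat(sprintf("raster_grid: %d x %d cells, %.0f m cell size, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin[1], x$origin[2]))
  cat(sprintf("  valid cells: %d (%.1f%%), range [%.4g, %.4g]\n",
              length(v), 100 * length(v) / length(x$values),
              suppressWarnings(min(v)), suppressWarnings(max(v))))
  invisible(x)
}

#' @rdname raster_grid
#' @param x object to test.
#' @export
is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Check that two grids share the same lattice
#'
#' Grids are compatible when they agree in shape, origin and cell size; every
#' multi-layer operation in the package requires this.
#'
#' @param a,b `raster_grid` objects.
#' @param tol numeric tolerance on origin/cell size.
#' @return `TRUE` or `FALSE`.
#' @export
grid_compatible <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_if_incompatible <- function(a, b, what = "rasters") {
  if (!grid_compatible(a, b)) {
    stop(sprintf("%s are not grid-compatible (shape/origin/cell size differ)",
                 what))
  }
  invisible(TRUE)
}

#' Cell centre coordinates and inverse lookup
#'
#' `cell_centers` returns the map coordinates of the centres of the given
#' cells; `locate_cells` returns the (row, col) indices of the cells
#' containing the given points.
#'
#' @param grid a `raster_grid`.
#' @param rows,cols integer cell indices (recycled together).
#' @return `cell_centers`: a two-column matrix `x`,`y`;
#'   `locate_cells`: a two-column matrix `row`,`col` (NA outside the grid).
#' @export
cell_centers <- function(grid, rows, cols) {
  nr <- nrow(grid$values)
  cs <- grid$cell_size
  cbind(x = grid$origin[1] + (cols - 0.5) * cs,
        y = grid$origin[2] + (nr - rows + 0.5) * cs)
}

#' @rdname cell_centers
#' @param x,y point coordinates in map units.
#' @export
locate_cells <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cs <- grid$cell_size
  col <- floor((x - grid$origin[1]) / cs) + 1L
  row <- nr - floor((y - grid$origin[2]) / cs)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Valid-cell mask
#'
#' @param grid a `raster_grid`.
#' @return logical matrix, `TRUE` where the cell carries data (not nodata and
#'   finite).
#' @export
valid_mask <- function(grid) {
  !grid$nodata & is.finite(grid$values)
}

#' Predictor stacks
#'
#' An ordered, named collection of grid-compatible raster layers used as
#' environmental predictors.
#'
#' @param layers named list of `raster_grid` objects.
#' @return an object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers) {
  if (length(layers) < 1) stop("a predictor stack needs at least one layer")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("layers must have unique non-empty names")
  }
  for (i in seq_along(layers)) {
    if (!is_raster_grid(layers[[i]])) stop("all layers must be raster_grid")
    if (!grid_compatible(layers[[1]], layers[[i]])) {
      stop(sprintf("layer '%s' is not grid-compatible with layer '%s'",
                   nm[i], nm[1]))
    }
  }
  structure(list(layers = layers, names = nm), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers (%s)\n", length(x$layers),
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Presence point sets
#'
#' Species-labelled point records (map coordinates of observed presences, or
#' of generated pseudo-absences).
#'
#' @param species species name.
#' @param x,y numeric point coordinates (map units, cell-centre based).
#' @param source_label provenance label: `"sighting"`, `"sign"` or
#'   `"absence"`.
#' @return an object of class `presence_set`.
#' @export
presence_set <- function(species, x = numeric(0), y = numeric(0),
                         source_label = "sighting") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  structure(list(species = species, x = as.numeric(x), y = as.numeric(y),
                 source_label = source_label),
            class = "presence_set")
}

#' @export
print.presence_set <- function(x, ...) {
  cat(sprintf("presence_set: %s, %d points (%s)\n",
              x$species, length(x$x), x$source_label))
  invisible(x)
}

#' Number of points in a presence set
#' @param ps a `presence_set`.
#' @export
n_points <- function(ps) length(ps$x)

#' Terminal regions
#'
#' One of the two reserves between which connectivity is computed, as a
#' boolean mask on the shared grid.
#'
#' @param name terminal name.
#' @param mask logical matrix on the shared grid.
#' @param grid the `raster_grid` the mask lives on.
#' @return an object of class `terminal_region`.
#' @export
terminal_region <- function(name, mask, grid) {
  if (!identical(dim(mask), dim(grid$values))) {
    stop("terminal mask must match grid dimensions")
  }
  mask <- mask & valid_mask(grid)
  if (!any(mask)) stop(sprintf("terminal '%s' is empty (or entirely nodata)",
                               name))
  structure(list(name = name, mask = mask), class = "terminal_region")
}

#' @export
print.terminal_region <- function(x, ...) {
  cat(sprintf("terminal_region: %s, %d cells\n", x$name, sum(x$mask)))
  invisible(x)
}
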