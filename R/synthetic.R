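# Seeded synthetic landscapes: smooth environmental fields, distance-to-
# feature fields, known species-habitat relationships and transect-sampled
# presences. Every generator is a pure function of its arguments including
# the seed.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Separable Gaussian smoothing with reflected edges; kernel truncated at
# 3 sd. Used only as an autocorrelation-inducing filter, so the exact
# truncation radius is not load-bearing.
gaussian_smooth <- function(m, sd_cells) {
  r <- max(1L, ceiling(3 * sd_cells))
  k <- stats::dnorm(seq(-r, r), sd = sd_cells)
  k <- k / sum(k)
  reflect_idx <- function(n) {
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - seq_len(min(r, n)))
    if (r > n) { # tiny grids: recycle the reflection
      idx <- c(rep(1L, r - n), idx[idx >= 1], rep(n, r - n))
    }
    idx
  }
  conv1 <- function(mat) { # smooth down columns
    n <- nrow(mat)
    padded <- mat[reflect_idx(n), , drop = FALSE]
    out <- matrix(0, n, ncol(mat))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

standardize_layer <- function(grid) {
  ok <- valid_mask(grid)
  v <- grid$values[ok]
  s <- stats::sd(v)
  if (s == 0) stop("cannot standardize a constant layer")
  grid$values[ok] <- (v - mean(v)) / s
  grid$values[!ok] <- 0
  grid
}

#' Generate a synthetic predictor stack
#'
#' Builds seeded environmental predictor layers on a shared lattice: smooth
#' fields (Gaussian-filtered white noise, emulating vegetation indices and
#' land-cover percentages) and distance fields (exact Euclidean distance
#' from a few random feature points, emulating distances to settlements,
#' rivers or reserves). Every layer is standardized to zero mean and unit
#' variance over valid cells.
#'
#' @param shape integer length-2 (rows, cols), or a single integer for a
#'   square grid. Must be at least 10 x 10.
#' @param cell_size cell edge length in metres (default 1000 m, the transect
#'   grid resolution the sampler assumes).
#' @param n_smooth_fields,n_distance_fields how many layers of each kind.
#' @param seed integer seed; the stack is a pure function of the arguments.
#' @param smooth_sd spatial autocorrelation range of the smooth fields, in
#'   cells (Gaussian kernel sd).
#' @param n_feature_points feature points per distance field.
#' @param nodata optional logical nodata matrix.
#' @return a `predictor_stack` with layers named `smooth1..k, dist1..m`.
#' @export
make_predictor_stack <- function(shape, cell_size = 1000,
                                 n_smooth_fields = 2, n_distance_fields = 2,
                                 seed = 1, smooth_sd = 5,
                                 n_feature_points = 3, nodata = NULL) {
  if (length(shape) == 1) shape <- c(shape, shape)
  shape <- as.integer(shape)
  if (any(shape < 10)) stop("shape must be at least 10 x 10")
  if (n_smooth_fields < 0 || n_distance_fields < 0 ||
      n_smooth_fields + n_distance_fields < 1) {
    stop("at least one predictor layer must be requested")
  }
  nr <- shape[1]; nc <- shape[2]
  base <- raster_grid(matrix(0, nr, nc), cell_size = cell_size,
                      nodata = nodata)
  with_seed(seed, {
    layers <- list()
    for (i in seq_len(n_smooth_fields)) {
      noise <- matrix(stats::rnorm(nr * nc), nr, nc)
      g <- base
      g$values <- gaussian_smooth(noise, smooth_sd)
      layers[[paste0("smooth", i)]] <- standardize_layer(g)
    }
    for (i in seq_len(n_distance_fields)) {
      feat <- cbind(row = sample.int(nr, n_feature_points, replace = TRUE),
                    col = sample.int(nc, n_feature_points, replace = TRUE))
      g <- base
      g$values <- distance_field(base, feat)
      layers[[paste0("dist", i)]] <- standardize_layer(g)
    }
    predictor_stack(layers)
  })
}

#' Exact Euclidean distance field from feature cells
#'
#' @param grid template `raster_grid`.
#' @param features two-column matrix of (row, col) feature cell indices.
#' @return matrix of distances (map units) from each cell centre to the
#'   nearest feature cell centre.
#' @export
distance_field <- function(grid, features) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- matrix(Inf, nr, nc)
  for (f in seq_len(nrow(features))) {
    d2 <- pmin(d2, (rows - features[f, 1])^2 + (cols - features[f, 2])^2)
  }
  sqrt(d2) * grid$cell_size
}

#' Place the two terminal reserves
#'
#' Default placement mirrors a two-reserve landscape: square blocks in the
#' north-west and south-east corners, each covering about `frac` of the grid.
#' Custom placement accepts a list of two logical masks.
#'
#' @param grid a `raster_grid`.
#' @param placement `"corners"` or a list of two logical masks.
#' @param frac target fraction of cells per terminal (corner placement).
#' @param names terminal names.
#' @return list of two disjoint `terminal_region` objects.
#' @export
make_terminals <- function(grid, placement = "corners", frac = 0.05,
                           names = c("reserve_a", "reserve_b")) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  if (is.character(placement) && placement == "corners") {
    side <- max(1L, round(sqrt(frac * nr * nc)))
    side <- min(side, nr, nc)
    a <- matrix(FALSE, nr, nc); a[seq_len(side), seq_len(side)] <- TRUE
    b <- matrix(FALSE, nr, nc)
    b[nr - seq_len(side) + 1L, nc - seq_len(side) + 1L] <- TRUE
  } else if (is.list(placement) && length(placement) == 2) {
    a <- placement[[1]]; b <- placement[[2]]
  } else stop("placement must be \"corners\" or a list of two masks")
  if (any(a & b)) stop("terminal masks overlap")
  ta <- terminal_region(names[1], a, grid)
  tb <- terminal_region(names[2], b, grid)
  if (any(ta$mask & tb$mask)) stop("terminal masks overlap")
  list(ta, tb)
}

#' Synthetic species specifications
#'
#' A known species-habitat relationship on the log-odds scale, used as
#' ground truth for parameter-recovery tests: presence probability is
#' `plogis(intercept + sum(coefficients * predictors))`.
#'
#' @param name species name.
#' @param coefficients named numeric vector, one per predictor layer.
#' @param intercept log-odds intercept.
#' @param detection_scale per-visit detection probability scaling in (0, 1].
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(name, coefficients, intercept = 0,
                         detection_scale = 1) {
  if (all(coefficients == 0)) {
    stop("at least one coefficient must be nonzero")
  }
  if (detection_scale <= 0 || detection_scale > 1) {
    stop("detection_scale must be in (0, 1]")
  }
  structure(list(name = name, coefficients = coefficients,
                 intercept = intercept, detection_scale = detection_scale),
            class = "species_spec")
}

#' True suitability surface of a synthetic species
#'
#' @param spec a `species_spec` whose coefficient names match the predictor
#'   layer names.
#' @param predictors a `predictor_stack`.
#' @return a `raster_grid` of presence probabilities in (0, 1).
#' @export
true_suitability <- function(spec, predictors) {
  cn <- names(spec$coefficients)
  if (is.null(cn) || !setequal(cn, predictors$names)) {
    stop("coefficient names must match predictor layer names")
  }
  g <- predictors$layers[[1]]
  eta <- matrix(spec$intercept, nrow(g$values), ncol(g$values))
  for (nm in cn) {
    eta <- eta + spec$coefficients[[nm]] * predictors$layers[[nm]]$values
  }
  out <- g
  out$values <- stats::plogis(eta)
  out$values[!valid_mask(g)] <- 0
  out
}

#' Sample presences along north-south transects
#'
#' Emulates single-visit line-transect presence data: parallel north-south
#' transects separated by `transect_spacing` bisect the grid columns; each
#' cell a transect crosses yields a presence with probability
#' `detection_scale * truth(cell)`, placed at the cell centre with a small
#' uniform jitter inside the cell.
#'
#' @param truth `raster_grid` of true presence probabilities in \[0, 1\].
#' @param transect_spacing spacing between transects (m); must be a positive
#'   integer multiple of the cell size.
#' @param detection_scale detection probability multiplier in (0, 1\].
#' @param seed integer seed.
#' @param species species label for the returned set.
#' @return a `presence_set`.
#' @export
sample_transect_presences <- function(truth, transect_spacing = NULL,
                                      detection_scale = 1, seed = 1,
                                      species = "synthetic") {
  cs <- truth$cell_size
  if (is.null(transect_spacing)) transect_spacing <- cs
  if (transect_spacing < cs) stop("transect spacing must be >= cell size")
  step <- transect_spacing / cs
  if (abs(step - round(step)) > 1e-9) {
    stop("transect spacing must be an integer multiple of cell size")
  }
  nr <- nrow(truth$values); nc <- ncol(truth$values)
  cols <- seq(1L, nc, by = as.integer(round(step)))
  ok <- valid_mask(truth)
  with_seed(seed, {
    cells <- which(ok[, cols, drop = FALSE], arr.ind = TRUE)
    rows_all <- cells[, 1]
    cols_all <- cols[cells[, 2]]
    p <- detection_scale * truth$values[cbind(rows_all, cols_all)]
    hit <- stats::runif(length(p)) < p
    rows_hit <- rows_all[hit]; cols_hit <- cols_all[hit]
    ctr <- cell_centers(truth, rows_hit, cols_hit)
    jit <- function(n) stats::runif(n, -0.45, 0.45) * cs
    presence_set(species,
                 ctr[, "x"] + jit(length(rows_hit)),
                 ctr[, "y"] + jit(length(rows_hit)),
                 source_label = "sighting")
  })
}

#' Plant a known high-suitability corridor
#'
#' Builds a suitability fixture whose optimal corridor is known by
#' construction: an L-shaped channel of high suitability `high` runs from
#' the north-west terminal east along the top of the grid and then south
#' along the east edge to the south-east terminal, through a uniform matrix
#' of suitability `high / contrast`. The channel cell mask is recorded in
#' the `"channel"` attribute for tests.
#'
#' @param shape grid shape as in [make_predictor_stack()].
#' @param channel_width channel width in cells.
#' @param contrast ratio of channel to matrix suitability; must exceed 1.
#' @param cell_size cell edge length (m).
#' @param high channel suitability value in (0, 1).
#' @return a `raster_grid` with attribute `"channel"` (logical matrix).
#' @export
plant_corridor_landscape <- function(shape, channel_width = 2, contrast = 10,
                                     cell_size = 1000, high = 0.9) {
  if (length(shape) == 1) shape <- c(shape, shape)
  shape <- as.integer(shape)
  if (contrast <= 1) stop("contrast must exceed 1")
  if (channel_width >= min(shape)) stop("channel wider than grid")
  if (high <= 0 || high >= 1) stop("high must be in (0, 1)")
  nr <- shape[1]; nc <- shape[2]
  chan <- matrix(FALSE, nr, nc)
  chan[seq_len(channel_width), ] <- TRUE               # north band
  chan[, nc - seq_len(channel_width) + 1L] <- TRUE     # east band
  v <- matrix(high / contrast, nr, nc)
  v[chan] <- high
  g <- raster_grid(v, cell_size = cell_size)
  attr(g, "channel") <- chan
  g
}
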