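#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange. Writing then reading a grid reproduces the
#' values, mask, origin and cell size exactly (values are printed at full
#' double precision). Cells under the nodata mask are written as the
#' `NODATA_value`; on reading, cells equal to the declared `NODATA_value` are
#' masked.
#'
#' @param grid a `raster_grid`.
#' @param path file path (conventionally `.asc`).
#' @param nodata_value sentinel written for masked cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `raster_grid`.
#' @export
write_ascii_grid <- function(grid, path, nodata_value = -9999) {
  v <- grid$values
  v[grid$nodata] <- nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", nodata_value))
  rows <- apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs_label label attached to the grid on read.
#' @export
read_ascii_grid <- function(path, crs_label = "local-equal-area") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop(sprintf("malformed ESRI ASCII header in %s", path))
  }
  nodv <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (is.na(nodv)) matrix(FALSE, nr, nc) else m == nodv
  m[nodata] <- 0
  raster_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner),
              cell_size = hdr$cellsize, nodata = nodata,
              crs_label = crs_label)
}

#' Read and write a predictor stack as a directory of ASCII grids
#'
#' Each layer is one `<name>.asc` file. On read, all layers must share shape,
#' origin and cell size; a mismatch is reported with the offending layer
#' named.
#'
#' @param stack a `predictor_stack`.
#' @param dir directory path.
#' @return `write_stack_dir` returns `dir` invisibly; `read_stack_dir`
#'   returns a `predictor_stack` (layers in alphabetical order unless
#'   `layer_names` is given).
#' @export
write_stack_dir <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in stack$names) {
    write_ascii_grid(stack$layers[[nm]], file.path(dir, paste0(nm, ".asc")))
  }
  invisible(dir)
}

#' @rdname write_stack_dir
#' @param layer_names optional layer order; default all `.asc` files sorted.
#' @export
read_stack_dir <- function(dir, layer_names = NULL) {
  if (is.null(layer_names)) {
    layer_names <- sort(sub("\\.asc$", "", list.files(dir, "\\.asc$")))
  }
  if (length(layer_names) == 0) stop(sprintf("no .asc layers found in %s", dir))
  layers <- list()
  for (nm in layer_names) {
    g <- read_ascii_grid(file.path(dir, paste0(nm, ".asc")))
    if (length(layers) > 0 && !grid_compatible(layers[[1]], g)) {
      stop(sprintf("layer '%s' does not match the grid of layer '%s'",
                   nm, names(layers)[1]))
    }
    layers[[nm]] <- g
  }
  predictor_stack(layers)
}

#' Read and write presence points as CSV
#'
#' The interchange format is a plain CSV with header `species,x,y` (an
#' optional `source` column carries the provenance label).
#'
#' @param ps a `presence_set` (or list of them, concatenated on write).
#' @param path CSV file path.
#' @return `write_presences_csv` returns `path` invisibly;
#'   `read_presences_csv` returns a named list of `presence_set`, one per
#'   species present in the file.
#' @export
write_presences_csv <- function(ps, path) {
  if (inherits(ps, "presence_set")) ps <- list(ps)
  df <- do.call(rbind, lapply(ps, function(p) {
    if (n_points(p) == 0) return(NULL)
    data.frame(species = p$species, x = p$x, y = p$y, source = p$source_label)
  }))
  if (is.null(df)) df <- data.frame(species = character(0), x = numeric(0),
                                    y = numeric(0), source = character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presences_csv
#' @export
read_presences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "x", "y") %in% names(df))) {
    stop("presence CSV must have columns species,x,y")
  }
  if (is.null(df$source)) df$source <- "sighting"
  out <- list()
  for (sp in unique(df$species)) {
    sub <- df[df$species == sp, ]
    out[[sp]] <- presence_set(sp, sub$x, sub$y,
                              source_label = sub$source[1])
  }
  out
}

#' Write a terminal region as a 0/1 ASCII grid
#'
#' @param term a `terminal_region`.
#' @param grid the shared `raster_grid` (for georeferencing).
#' @param path file path.
#' @export
write_terminal <- function(term, grid, path) {
  g <- raster_grid(term$mask * 1, origin = grid$origin,
                   cell_size = grid$cell_size, crs_label = grid$crs_label)
  write_ascii_grid(g, path)
}

#' @rdname write_terminal
#' @param name terminal name to attach on read.
#' @export
read_terminal <- function(path, grid, name = "terminal") {
  g <- read_ascii_grid(path)
  if (!grid_compatible(g, grid)) stop("terminal raster does not match grid")
  terminal_region(name, g$values > 0.5 & !g$nodata, grid)
}
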