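# Connectivity between two terminal reserves on a resistance raster.
# Valid cells are graph nodes; 8-neighbour moves carry cost
# ((r_i + r_j) / 2) * d, with d = cell length for rook moves and
# cell length * sqrt(2) for diagonal moves, in km. Terminals are contracted
# to zero-internal-cost supernodes. The least-cost branch yields
# cost-weighted distances and the normalized corridor; the circuit branch
# solves the graph Laplacian for voltages, currents and effective
# resistance.

#' Build the movement graph for a resistance surface
#'
#' @param res a `resistance_surface`.
#' @param a,b `terminal_region` objects on the same grid (disjoint).
#' @param connectivity 8 (default, with sqrt(2)-scaled diagonals) or 4.
#' @return an object of class `movement_graph`: an edge table in contracted
#'   node ids (terminal supernodes), plus the cell-to-node map.
#' @export
build_graph <- function(res, a, b, connectivity = 8) {
  g <- res$grid
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (any(a$mask & b$mask)) stop("terminals must be disjoint")
  ok <- valid_mask(g)
  if (!any(a$mask & ok) || !any(b$mask & ok)) stop("terminal is empty")
  nr <- nrow(g$values); nc <- ncol(g$values)
  cell_km <- g$cell_size / 1000

  # contracted node ids: non-terminal valid cells 1..m, then supernodes
  node_of <- matrix(NA_integer_, nr, nc)
  interior <- ok & !a$mask & !b$mask
  m <- sum(interior)
  node_of[interior] <- seq_len(m)
  node_a <- m + 1L; node_b <- m + 2L
  node_of[ok & a$mask] <- node_a
  node_of[ok & b$mask] <- node_b

  offsets <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)

  from_cell <- integer(0); to_cell <- integer(0); cost <- numeric(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
    i1 <- as.vector(outer(r1, (c1 - 1) * nr, `+`))           # linear index
    i2 <- i1 + dr + dc * nr
    keep <- ok[i1] & ok[i2]
    i1 <- i1[keep]; i2 <- i2[keep]
    d <- if (dr != 0 && dc != 0) cell_km * sqrt(2) else cell_km
    from_cell <- c(from_cell, i1)
    to_cell <- c(to_cell, i2)
    cost <- c(cost, (g$values[i1] + g$values[i2]) / 2 * d)
  }
  from_node <- node_of[from_cell]
  to_node <- node_of[to_cell]
  # drop edges internal to one terminal (contracted away, internal cost 0)
  internal <- from_node == to_node
  structure(
    list(edges = data.frame(from_cell = from_cell[!internal],
                            to_cell = to_cell[!internal],
                            from_node = from_node[!internal],
                            to_node = to_node[!internal],
                            cost = cost[!internal]),
         node_of = node_of, n_interior = m,
         node_a = node_a, node_b = node_b,
         terminal_names = c(a$name, b$name),
         grid = g, cell_km = cell_km, connectivity = connectivity),
    class = "movement_graph")
}

#' @export
print.movement_graph <- function(x, ...) {
  cat(sprintf("movement_graph: %d interior nodes + 2 terminals, %d edges (%d-connected)\n",
              x$n_interior, nrow(x$edges), x$connectivity))
  invisible(x)
}

terminal_node <- function(g, from) {
  if (identical(from, "a") || identical(from, g$terminal_names[1])) return(g$node_a)
  if (identical(from, "b") || identical(from, g$terminal_names[2])) return(g$node_b)
  stop(sprintf("unknown terminal '%s'", from))
}

igraph_of <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = g$edges$from_node, to = g$edges$to_node),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g$n_interior + 2L)))
}

#' Cost-weighted distance from a terminal
#'
#' Exact single-source shortest-path cost (Dijkstra) from the contracted
#' terminal supernode to every cell, in cost-weighted km. Terminal cells are
#' at distance 0; unreachable cells are `Inf`.
#'
#' @param g a `movement_graph`.
#' @param from `"a"`, `"b"`, or a terminal name.
#' @return an object of class `cwd_map` (fields `grid`, `terminal_name`);
#'   the grid's values are the cost-weighted distances.
#' @export
cost_distance <- function(g, from = "a") {
  src <- terminal_node(g, from)
  ig <- igraph_of(g)
  d <- igraph::distances(ig, v = as.character(src), weights = g$edges$cost,
                         algorithm = "dijkstra")
  d <- d[1, as.character(seq_len(g$n_interior + 2L))]
  vals <- matrix(NA_real_, nrow(g$grid$values), ncol(g$grid$values))
  okcells <- !is.na(g$node_of)
  vals[okcells] <- d[g$node_of[okcells]]
  out <- g$grid
  out$values <- vals
  out$values[!okcells] <- 0
  out$nodata <- !okcells
  # grid invariant wants finite values off-nodata; keep Inf as values but
  # bypass the constructor check by assigning directly
  structure(list(grid = out,
                 terminal_name = if (src == g$node_a) g$terminal_names[1]
                                 else g$terminal_names[2]),
            class = "cwd_map")
}

#' @export
print.cwd_map <- function(x, ...) {
  cat(sprintf("cwd_map: from %s\n", x$terminal_name))
  invisible(x)
}

#' Normalized least-cost corridor and quantile slice
#'
#' The corridor surface is `CWD_A + CWD_B - LCP` where LCP is the least-cost
#' path cost between the terminals (the minimum of the sum); it is zero
#' along every optimal path. Cells inside either terminal reserve (CWD = 0)
#' are not part of the corridor surface: the corridor maps the land between
#' the reserves, so reserve cells are masked out before slicing. The binary
#' corridor keeps the lowest `slice_fraction` of finite corridor cells by
#' area (ties at the boundary are all included); `mode = "cost_ratio"`
#' instead keeps cells with corridor value at most `slice_fraction * LCP`.
#'
#' @param cwd_a,cwd_b `cwd_map` objects from opposite terminals on the same
#'   grid.
#' @param slice_fraction fraction in (0, 1\] (default 0.10, the 10% least-
#'   cost corridor).
#' @param mode `"area"` (default) or `"cost_ratio"`.
#' @return an object of class `corridor_result`: `nlcc` (raster of the
#'   normalized corridor), `lcp_cost`, `mask` (logical corridor matrix),
#'   `slice_fraction`, `mode`.
#' @export
least_cost_corridor <- function(cwd_a, cwd_b, slice_fraction = 0.10,
                                mode = c("area", "cost_ratio")) {
  mode <- match.arg(mode)
  stop_if_incompatible(cwd_a$grid, cwd_b$grid, "CWD maps")
  if (slice_fraction <= 0 || slice_fraction > 1) {
    stop("slice_fraction must be in (0, 1]")
  }
  total <- cwd_a$grid$values + cwd_b$grid$values
  in_terminal <- cwd_a$grid$values == 0 | cwd_b$grid$values == 0
  ok <- valid_mask(cwd_a$grid) & valid_mask(cwd_b$grid) &
    is.finite(total) & !in_terminal
  if (!any(ok)) stop("terminals are disconnected: no finite corridor cell")
  lcp <- min(total[ok])
  nlcc_vals <- total - lcp
  nlcc_vals[!ok] <- 0
  out <- cwd_a$grid
  out$values <- nlcc_vals
  out$nodata <- !ok
  finite_vals <- nlcc_vals[ok]
  thr <- if (mode == "area") {
    sort(finite_vals)[ceiling(slice_fraction * length(finite_vals))]
  } else slice_fraction * lcp
  mask <- ok & (nlcc_vals <= thr)
  structure(list(nlcc = out, lcp_cost = lcp, mask = mask,
                 slice_fraction = slice_fraction, mode = mode,
                 threshold = thr),
            class = "corridor_result")
}

#' @export
print.corridor_result <- function(x, ...) {
  cat(sprintf("corridor_result: LCP cost %.3f, %d corridor cells (%.1f%% slice, %s mode)\n",
              x$lcp_cost, sum(x$mask), 100 * x$slice_fraction, x$mode))
  invisible(x)
}

#' Circuit-theory connectivity between two terminals
#'
#' Treats each movement-graph edge as a resistor of resistance equal to its
#' traversal cost (conductance 1/cost), fixes the source supernode at
#' voltage 1 and the ground supernode at 0, and solves the interior
#' Kirchhoff equations (the reduced graph Laplacian, a sparse symmetric
#' positive-definite system). Per-cell current is half the sum of absolute
#' currents on incident edges, reported for one unit of injected current —
#' a measure of how much random-walk movement funnels through the cell,
#' invariant to uniform rescaling of the resistance surface. Effective
#' resistance is 1 over the total source outflow of the unit-voltage
#' solution.
#'
#' @param g a `movement_graph`.
#' @param source,ground `"a"`, `"b"`, or terminal names.
#' @return an object of class `circuit_result`: `voltage` and `current`
#'   rasters, scalar `effective_resistance` (Inf when the terminals are
#'   disconnected), and `total_current`.
#' @export
circuit_solve <- function(g, source = "a", ground = "b") {
  src <- terminal_node(g, source)
  gnd <- terminal_node(g, ground)
  if (src == gnd) stop("source and ground must differ")
  n <- g$n_interior + 2L
  cond <- 1 / g$edges$cost

  # connectivity check: is there any path source -> ground?
  ig <- igraph_of(g)
  comp <- igraph::components(ig)$membership
  if (comp[src] != comp[gnd]) {
    empty <- g$grid
    empty$values[] <- NA_real_
    return(structure(list(voltage = NULL, current = NULL,
                          effective_resistance = Inf, total_current = 0,
                          connected = FALSE),
                     class = "circuit_result"))
  }

  i <- g$edges$from_node; j <- g$edges$to_node
  # graph Laplacian (summing parallel edge conductances implicitly)
  L <- Matrix::sparseMatrix(i = c(i, j, i, j), j = c(j, i, i, j),
                            x = c(-cond, -cond, cond, cond),
                            dims = c(n, n))
  unknown <- setdiff(seq_len(n), c(src, gnd))
  v <- numeric(n)
  v[src] <- 1; v[gnd] <- 0
  if (length(unknown) > 0) {
    rhs <- -as.numeric(L[unknown, src]) # ground column contributes 0
    sol <- Matrix::solve(L[unknown, unknown, drop = FALSE], rhs)
    v[unknown] <- as.numeric(sol)
  }

  edge_current <- cond * (v[i] - v[j])
  total_out <- sum(abs(edge_current[i == src | j == src]))
  # report current for unit injected current (normalize the fixed-voltage
  # solution by the total source outflow): the current map is then
  # invariant to a uniform rescaling of the resistance surface
  edge_current <- edge_current / total_out
  # per-cell current: attribute each edge's current to its original cells
  cur <- matrix(0, nrow(g$grid$values), ncol(g$grid$values))
  add_abs <- function(cells, amounts) {
    agg <- rowsum(amounts, cells)
    cur[as.integer(rownames(agg))] <<- cur[as.integer(rownames(agg))] + agg[, 1]
  }
  add_abs(g$edges$from_cell, abs(edge_current))
  add_abs(g$edges$to_cell, abs(edge_current))
  cur <- cur / 2

  okcells <- !is.na(g$node_of)
  volt <- matrix(0, nrow(cur), ncol(cur))
  volt[okcells] <- v[g$node_of[okcells]]

  vg <- g$grid; vg$values <- volt; vg$nodata <- !okcells
  cg <- g$grid; cg$values <- cur; cg$nodata <- !okcells
  structure(list(voltage = vg, current = cg,
                 effective_resistance = 1 / total_out,
                 total_current = total_out, connected = TRUE,
                 source = g$terminal_names[if (src == g$node_a) 1 else 2],
                 ground = g$terminal_names[if (gnd == g$node_a) 1 else 2]),
            class = "circuit_result")
}

#' @export
print.circuit_result <- function(x, ...) {
  if (!x$connected) {
    cat("circuit_result: terminals disconnected (effective resistance Inf)\n")
  } else {
    cat(sprintf("circuit_result: %s -> %s, effective resistance %.4f\n",
                x$source, x$ground, x$effective_resistance))
  }
  invisible(x)
}

#' Run both connectivity methods for one resistance surface
#'
#' Convenience orchestration: builds the movement graph once, computes
#' cost-weighted distances from both terminals, the normalized corridor
#' with its quantile slice, and the circuit solution.
#'
#' @inheritParams build_graph
#' @param slice_fraction corridor slice fraction.
#' @param methods subset of `c("least_cost", "circuit")`.
#' @return list with elements `corridor` (a `corridor_result`), `circuit`
#'   (a `circuit_result`), `cwd_a`, `cwd_b` (present when the least-cost
#'   branch ran).
#' @export
run_species_connectivity <- function(res, a, b, slice_fraction = 0.10,
                                     connectivity = 8,
                                     methods = c("least_cost", "circuit")) {
  g <- build_graph(res, a, b, connectivity = connectivity)
  out <- list()
  if ("least_cost" %in% methods) {
    out$cwd_a <- cost_distance(g, "a")
    out$cwd_b <- cost_distance(g, "b")
    out$corridor <- least_cost_corridor(out$cwd_a, out$cwd_b, slice_fraction)
  }
  if ("circuit" %in% methods) {
    out$circuit <- circuit_solve(g, "a", "b")
  }
  out
}
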