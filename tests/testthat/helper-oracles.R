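# Independent brute-force oracles. These re-derive the movement-graph and
# solver results from first principles with naive loops, deliberately
# sharing no code with the package implementations they check.

# Enumerate movement edges by scanning every cell and every neighbour
# offset. Terminals are contracted by a naive node-relabelling pass.
# Returns 1-based node ids: interior cells keep individual ids, terminal A
# and B collapse to two extra ids.
oracle_graph <- function(rmat, cell_size = 1000, nodata = NULL,
                         a_mask = NULL, b_mask = NULL, connectivity = 8) {
  nr <- nrow(rmat); nc <- ncol(rmat)
  if (is.null(nodata)) nodata <- matrix(FALSE, nr, nc)
  if (is.null(a_mask)) a_mask <- matrix(FALSE, nr, nc)
  if (is.null(b_mask)) b_mask <- matrix(FALSE, nr, nc)
  cell_km <- cell_size / 1000
  node_of <- matrix(NA_integer_, nr, nc)
  nid <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!nodata[rr, cc] && !a_mask[rr, cc] && !b_mask[rr, cc]) {
      nid <- nid + 1L
      node_of[rr, cc] <- nid
    }
  }
  node_a <- nid + 1L; node_b <- nid + 2L
  node_of[a_mask & !nodata] <- node_a
  node_of[b_mask & !nodata] <- node_b
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (nodata[rr, cc]) next
    for (o in offs) {
      r2 <- rr + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (nodata[r2, c2]) next
      n1 <- node_of[rr, cc]; n2 <- node_of[r2, c2]
      if (n1 == n2) next                       # internal to a terminal
      if (n1 > n2) next                        # keep each pair once
      d <- if (all(o != 0)) cell_km * sqrt(2) else cell_km
      ei <- c(ei, n1); ej <- c(ej, n2)
      ew <- c(ew, (rmat[rr, cc] + rmat[r2, c2]) / 2 * d)
    }
  }
  # de-duplicate identical (i, j) pairs arising from scanning both cells,
  # but KEEP parallel supernode edges (same pair via different cells)
  list(i = ei, j = ej, w = ew, n = node_b, node_of = node_of,
       node_a = node_a, node_b = node_b)
}

# Bellman-Ford single-source shortest paths by repeated full relaxation.
oracle_bellman_ford <- function(g, src) {
  d <- rep(Inf, g$n)
  d[src] <- 0
  i2 <- c(g$i, g$j); j2 <- c(g$j, g$i); w2 <- c(g$w, g$w)
  for (iter in seq_len(g$n + 1)) {
    cand <- d[i2] + w2
    best <- tapply(cand, j2, min)
    nd <- d
    idx <- as.integer(names(best))
    nd[idx] <- pmin(nd[idx], as.numeric(best))
    if (all(nd == d | (is.infinite(nd) & is.infinite(d)))) break
    d <- nd
  }
  d
}

# Dense graph-Laplacian pseudo-inverse solution of the two-terminal flow
# problem: effective resistance via R = (e_s - e_g)' L^+ (e_s - e_g), node
# voltages rescaled so v[src] = 1, v[gnd] = 0.
oracle_circuit <- function(g, src, gnd) {
  n <- g$n
  L <- matrix(0, n, n)
  for (k in seq_along(g$i)) {
    c_k <- 1 / g$w[k]
    i <- g$i[k]; j <- g$j[k]
    L[i, j] <- L[i, j] - c_k
    L[j, i] <- L[j, i] - c_k
    L[i, i] <- L[i, i] + c_k
    L[j, j] <- L[j, j] + c_k
  }
  Lp <- MASS::ginv(L)
  e <- rep(0, n); e[src] <- 1; e[gnd] <- -1
  reff <- drop(t(e) %*% Lp %*% e)
  vraw <- drop(Lp %*% e)
  v <- (vraw - vraw[gnd]) / (vraw[src] - vraw[gnd])
  list(effective_resistance = reff, voltage = v)
}

# Pairwise-enumeration AUC: count concordant presence/absence pairs, ties
# half.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sa <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (a in sa) {
    tot <- tot + if (p > a) 1 else if (p == a) 0.5 else 0
  }
  tot / (length(sp) * length(sa))
}

# Greedy min-distance thinning replay for a given visit order.
oracle_thin <- function(x, y, min_distance, order) {
  kept <- integer(0)
  for (i in order) {
    ok <- TRUE
    for (k in kept) {
      if (sqrt((x[i] - x[k])^2 + (y[i] - y[k])^2) < min_distance) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# --- shared fixtures -------------------------------------------------------

# resistance surface straight from a matrix of per-cell costs
mk_resistance <- function(m, cell_size = 1000, nodata = NULL) {
  resistance_surface(raster_grid(m, cell_size = cell_size, nodata = nodata),
                     scaling = "custom", source_species = "fixture")
}

# single-cell terminals in opposite corners of an nr x nc grid
corner_terminals <- function(grid, a_cell = c(1, 1),
                             b_cell = c(nrow(grid$values), ncol(grid$values))) {
  ma <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  mb <- ma
  ma[a_cell[1], a_cell[2]] <- TRUE
  mb[b_cell[1], b_cell[2]] <- TRUE
  list(terminal_region("a", ma, grid), terminal_region("b", mb, grid))
}

random_resistance_grid <- function(seed, max_side = 20, nodata_frac = 0.05) {
  set.seed(seed)
  nr <- sample(4:max_side, 1); nc <- sample(4:max_side, 1)
  m <- matrix(stats::runif(nr * nc, 0.5, 100), nr, nc)
  nod <- matrix(stats::runif(nr * nc) < nodata_frac, nr, nc)
  nod[1, 1] <- FALSE; nod[nr, nc] <- FALSE   # keep terminals valid
  list(m = m, nodata = nod, nr = nr, nc = nc)
}
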