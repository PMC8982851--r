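chain3 <- function(r = c(1, 1, 1)) {
  g <- raster_grid(matrix(r, 1, 3), cell_size = 1000)
  list(rs = mk_resistance(matrix(r, 1, 3)),
       a = terminal_region("a", matrix(c(TRUE, FALSE, FALSE), 1, 3), g),
       b = terminal_region("b", matrix(c(FALSE, FALSE, TRUE), 1, 3), g))
}

test_that("movement graph edge costs average resistances with diagonal scaling", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  g <- raster_grid(m, cell_size = 1000)
  tt <- corner_terminals(g, c(1, 1), c(2, 2))
  mg <- build_graph(mk_resistance(m), tt[[1]], tt[[2]])
  # rook edge (1,1)-(2,1): mean(1,3) * 1 km = 2
  rook <- mg$edges[mg$edges$from_cell == 1 & mg$edges$to_cell == 2, ]
  expect_equal(rook$cost, 2)
  # diagonal edge (1,1)-(2,2): mean(1,4) * sqrt(2)
  diag_e <- mg$edges[mg$edges$from_cell == 1 & mg$edges$to_cell == 4, ]
  expect_equal(diag_e$cost, 2.5 * sqrt(2))
  # nodata cells carry no edges
  nod <- matrix(FALSE, 3, 3); nod[2, 2] <- TRUE
  g3 <- raster_grid(matrix(1, 3, 3), cell_size = 1000, nodata = nod)
  tt3 <- corner_terminals(g3)
  mg3 <- build_graph(mk_resistance(matrix(1, 3, 3), nodata = nod),
                     tt3[[1]], tt3[[2]])
  centre <- 5 # linear index of (2,2)
  expect_false(any(mg3$edges$from_cell == centre |
                     mg3$edges$to_cell == centre))
})

test_that("cost distance reproduces hand-computed chains", {
  ch <- chain3()
  cwd <- cost_distance(build_graph(ch$rs, ch$a, ch$b), "a")
  expect_equal(as.vector(cwd$grid$values), c(0, 1, 2))
  ch2 <- chain3(c(1, 99, 1))
  cwd2 <- cost_distance(build_graph(ch2$rs, ch2$a, ch2$b), "a")
  expect_equal(as.vector(cwd2$grid$values), c(0, 50, 100))
})

test_that("Dijkstra agrees with the Bellman-Ford oracle on random grids", {
  for (seed in 1:12) {
    rg <- random_resistance_grid(seed, max_side = 15)
    grid <- raster_grid(rg$m, cell_size = 1000, nodata = rg$nodata)
    tt <- corner_terminals(grid)
    mg <- build_graph(mk_resistance(rg$m, nodata = rg$nodata),
                      tt[[1]], tt[[2]])
    cwd <- cost_distance(mg, "a")
    og <- oracle_graph(rg$m, 1000, rg$nodata, tt[[1]]$mask, tt[[2]]$mask)
    d <- oracle_bellman_ford(og, og$node_a)
    ok <- !is.na(og$node_of)
    expect_lt(max(abs(cwd$grid$values[ok] - d[og$node_of[ok]]),
                  na.rm = TRUE), 1e-9)
  }
})

test_that("CWD satisfies the edge Lipschitz (triangle) property", {
  rg <- random_resistance_grid(77, max_side = 18)
  grid <- raster_grid(rg$m, cell_size = 1000, nodata = rg$nodata)
  tt <- corner_terminals(grid)
  mg <- build_graph(mk_resistance(rg$m, nodata = rg$nodata),
                    tt[[1]], tt[[2]])
  cwd <- cost_distance(mg, "a")
  node_d <- rep(NA_real_, mg$n_interior + 2)
  ok <- !is.na(mg$node_of)
  node_d[mg$node_of[ok]] <- cwd$grid$values[ok]
  viol <- abs(node_d[mg$edges$from_node] - node_d[mg$edges$to_node]) -
    mg$edges$cost
  expect_lt(max(viol), 1e-9)
})

test_that("corridor surface is zero on optimal paths and sliced by area", {
  pl <- plant_corridor_landscape(c(50, 50), channel_width = 2, contrast = 10)
  rs <- linear_resistance(suitability_map(pl, "fixture"))
  tt <- make_terminals(pl, frac = 0.05)
  out <- run_species_connectivity(rs, tt[[1]], tt[[2]])
  nl <- out$corridor$nlcc
  fin <- !nl$nodata
  expect_gte(min(nl$values[fin]), 0)
  expect_equal(min(nl$values[fin]), 0)
  # slice area: |mask| within ties of the 10% quantile cell count
  n_target <- ceiling(0.10 * sum(fin))
  ties <- sum(nl$values[fin] == out$corridor$threshold)
  expect_gte(sum(out$corridor$mask), n_target)
  expect_lte(sum(out$corridor$mask) - ties, n_target)
  # slice_fraction = 1 keeps every finite cell
  all_mask <- least_cost_corridor(out$cwd_a, out$cwd_b, 1)
  expect_equal(sum(all_mask$mask), sum(fin))
  # corridor excludes reserve interiors
  expect_false(any(out$corridor$mask & (tt[[1]]$mask | tt[[2]]$mask)))
})

test_that("circuit solver reproduces series and parallel resistor laws", {
  ch <- chain3()
  cc <- circuit_solve(build_graph(ch$rs, ch$a, ch$b))
  expect_equal(cc$effective_resistance, 2, tolerance = 1e-10)
  expect_equal(as.vector(cc$voltage$values), c(1, 0.5, 0),
               tolerance = 1e-10)
  # two disjoint chains of resistance 2 in parallel -> R_eff = 1
  nod <- matrix(FALSE, 3, 3); nod[2, ] <- TRUE
  g33 <- raster_grid(matrix(1, 3, 3), cell_size = 1000, nodata = nod)
  ma <- matrix(FALSE, 3, 3); ma[c(1, 3), 1] <- TRUE
  mb <- matrix(FALSE, 3, 3); mb[c(1, 3), 3] <- TRUE
  mg <- build_graph(mk_resistance(matrix(1, 3, 3), nodata = nod),
                    terminal_region("a", ma, g33),
                    terminal_region("b", mb, g33), connectivity = 4)
  expect_equal(circuit_solve(mg)$effective_resistance, 1,
               tolerance = 1e-10)
})

test_that("circuit voltages match the dense pseudo-inverse oracle", {
  for (seed in c(3, 8)) {
    rg <- random_resistance_grid(seed, max_side = 12, nodata_frac = 0)
    grid <- raster_grid(rg$m, cell_size = 1000)
    tt <- corner_terminals(grid)
    mg <- build_graph(mk_resistance(rg$m), tt[[1]], tt[[2]])
    cc <- circuit_solve(mg)
    og <- oracle_graph(rg$m, 1000, NULL, tt[[1]]$mask, tt[[2]]$mask)
    oc <- oracle_circuit(og, og$node_a, og$node_b)
    ok <- !is.na(og$node_of)
    expect_lt(max(abs(cc$voltage$values[ok] - oc$voltage[og$node_of[ok]])),
              1e-8)
    expect_equal(cc$effective_resistance, oc$effective_resistance,
                 tolerance = 1e-8)
  }
})

test_that("disconnected terminals give an explicit infinite resistance", {
  nod <- matrix(FALSE, 5, 5); nod[, 3] <- TRUE # wall splits the grid
  grid <- raster_grid(matrix(1, 5, 5), cell_size = 1000, nodata = nod)
  tt <- corner_terminals(grid)
  mg <- build_graph(mk_resistance(matrix(1, 5, 5), nodata = nod),
                    tt[[1]], tt[[2]])
  cc <- circuit_solve(mg)
  expect_false(cc$connected)
  expect_equal(cc$effective_resistance, Inf)
  cwd_a <- cost_distance(mg, "a"); cwd_b <- cost_distance(mg, "b")
  expect_true(any(is.infinite(cwd_a$grid$values)))
  expect_error(least_cost_corridor(cwd_a, cwd_b), "disconnected")
})

test_that("scaling resistance by k scales costs by k and leaves current invariant", {
  rg <- random_resistance_grid(21, max_side = 12, nodata_frac = 0)
  grid <- raster_grid(rg$m, cell_size = 1000)
  tt <- corner_terminals(grid)
  base <- run_species_connectivity(mk_resistance(rg$m), tt[[1]], tt[[2]])
  k <- 7.5
  scaled <- run_species_connectivity(mk_resistance(k * rg$m),
                                     tt[[1]], tt[[2]])
  expect_equal(scaled$corridor$lcp_cost, k * base$corridor$lcp_cost,
               tolerance = 1e-9)
  expect_equal(scaled$corridor$nlcc$values, k * base$corridor$nlcc$values,
               tolerance = 1e-9)
  expect_equal(scaled$circuit$effective_resistance,
               k * base$circuit$effective_resistance, tolerance = 1e-9)
  expect_equal(scaled$circuit$current$values, base$circuit$current$values,
               tolerance = 1e-8)
})

test_that("current respects the landscape's mirror symmetry on a uniform grid", {
  m <- matrix(1, 9, 9)
  grid <- raster_grid(m, cell_size = 1000)
  tt <- corner_terminals(grid) # corners lie on the NW-SE diagonal
  cc <- circuit_solve(build_graph(mk_resistance(m), tt[[1]], tt[[2]]))
  expect_lt(max(abs(cc$current$values - t(cc$current$values))), 1e-8)
})
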