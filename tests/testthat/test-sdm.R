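test_that("rank-based AUC matches pairwise enumeration and handles ties", {
  expect_equal(auc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auc(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(auc(c(0.2, 0.4), c(1, 1)), "both classes")
  # randomized cases against the pair-enumeration oracle, with ties
  set.seed(11)
  for (k in 1:20) {
    n <- sample(5:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
    # invariant to strictly monotone transforms of the scores
    expect_equal(auc(stats::qlogis(pmin(pmax(scores, 1e-3), 1 - 1e-3)),
                     labels),
                 auc(pmin(pmax(scores, 1e-3), 1 - 1e-3), labels))
  }
})

test_that("collinearity screen flags |r| above threshold and reports degeneracies", {
  g <- raster_grid(matrix(rnorm(100 * 100), 100, 100))
  neg <- g; neg$values <- -neg$values
  set.seed(2)
  indep <- raster_grid(matrix(rnorm(100 * 100), 100, 100))
  const <- raster_grid(matrix(1, 100, 100))
  ps <- predictor_stack(list(a = g, a_copy = g, a_neg = neg, b = indep,
                             flat = const))
  rep <- collinearity_screen(ps, threshold = 0.7)
  row_of <- function(x, y) rep[rep$layer_a == x & rep$layer_b == y, ]
  expect_equal(row_of("a", "a_copy")$r, 1.0)
  expect_true(row_of("a", "a_copy")$flagged)
  expect_equal(row_of("a", "a_neg")$r, -1.0)
  expect_true(row_of("a", "a_neg")$flagged)
  # two independent noise layers of 10^4 cells: null |r| < 0.05 (~ 5/sqrt(n))
  expect_lt(abs(row_of("a", "b")$r), 0.05)
  expect_false(row_of("a", "b")$flagged)
  expect_true(is.na(row_of("a", "flat")$r))
  expect_match(row_of("a", "flat")$note, "constant")
})

test_that("geographic thinning enforces the min-distance property exactly", {
  # two close points: one survives
  two <- presence_set("x", c(0, 10), c(0, 0))
  expect_equal(n_points(thin_points(two, 100, seed = 1)), 1)
  # zero distance: identity
  expect_equal(thin_points(two, 0, seed = 1), two)
  # 5x5 lattice at 1 km spacing, 1500 m radius: replay the greedy rule
  lat <- expand.grid(x = (0:4) * 1000, y = (0:4) * 1000)
  ps <- presence_set("x", lat$x, lat$y)
  thinned <- thin_points(ps, 1500, seed = 42)
  set.seed(42)
  ord <- sample.int(25)
  kept <- oracle_thin(lat$x, lat$y, 1500, ord)
  expect_equal(thinned$x, lat$x[kept])
  expect_equal(thinned$y, lat$y[kept])
  # property: all pairwise distances >= min_distance, random sets
  for (seed in 1:5) {
    set.seed(seed + 100)
    ps <- presence_set("x", runif(80, 0, 20000), runif(80, 0, 20000))
    th <- thin_points(ps, 2500, seed = seed)
    d <- as.matrix(stats::dist(cbind(th$x, th$y)))
    diag(d) <- Inf
    expect_gte(min(d), 2500)
  }
})

test_that("pseudo-absences avoid presence cells and respect availability", {
  g <- raster_grid(matrix(0, 100, 100), cell_size = 1000)
  pres <- presence_set("impala",
                       rep((1:37) * 1000 - 500, 1), rep(500, 37))
  pa <- generate_pseudo_absences(g, pres, "random_equal", seed = 1)
  expect_equal(n_points(pa), 37)           # one per presence
  expect_equal(pa$source_label, "absence")
  rc_p <- locate_cells(g, pres$x, pres$y)
  rc_a <- locate_cells(g, pa$x, pa$y)
  expect_equal(nrow(merge(as.data.frame(rc_p), as.data.frame(rc_a))), 0)
  # nearly-full grid: request exceeds available cells
  small <- raster_grid(matrix(0, 10, 10),
                       nodata = matrix(c(FALSE, rep(TRUE, 99)), 10, 10))
  expect_error(generate_pseudo_absences(small, presence_set("x"), "random",
                                        n = 2, seed = 1), "available")
  # uniformity: 10^4 draws from a 200x200 grid, per-quadrant 2500 +- 150
  g200 <- raster_grid(matrix(0, 200, 200), cell_size = 1000)
  pa2 <- generate_pseudo_absences(g200, presence_set("x"), "random",
                                  n = 10000, seed = 2)
  qx <- pa2$x > 100000; qy <- pa2$y > 100000
  counts <- table(qx, qy)
  expect_true(all(abs(counts - 2500) <= 150))
})

test_that("ensemble retains perfect learners on separable data", {
  ps <- make_predictor_stack(c(30, 30), 1000, 2, 0, seed = 5)
  l1 <- ps$layers$smooth1$values
  hi <- which(l1 > 1); lo <- which(l1 < -1)
  rc_hi <- arrayInd(hi, dim(l1)); rc_lo <- arrayInd(lo, dim(l1))
  ctr_hi <- cell_centers(ps$layers[[1]], rc_hi[, 1], rc_hi[, 2])
  ctr_lo <- cell_centers(ps$layers[[1]], rc_lo[, 1], rc_lo[, 2])
  pres <- presence_set("sep", ctr_hi[, "x"], ctr_hi[, "y"])
  abs <- presence_set("sep", ctr_lo[, "x"], ctr_lo[, "y"], "absence")
  fit <- fit_ensemble(pres, abs, ps, retention_auc = 0.90, reps = 3,
                      seed = 9)
  for (l in fit$model$learners) {
    expect_equal(l$mean_auc, 1.0, tolerance = 1e-9)
    expect_true(l$retained)
  }
  expect_equal(sum(fit$model$weights), 1)
  v <- fit$map$grid$values[valid_mask(fit$map$grid)]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("random labels give chance-level AUC and retention errors are informative", {
  ps <- make_predictor_stack(c(40, 40), 1000, 2, 0, seed = 6)
  g <- ps$layers[[1]]
  set.seed(31)
  cells <- sample(length(g$values), 1000)
  rc <- arrayInd(cells, dim(g$values))
  ctr <- cell_centers(g, rc[, 1], rc[, 2])
  pres <- presence_set("null", ctr[1:500, "x"], ctr[1:500, "y"])
  abs <- presence_set("null", ctr[501:1000, "x"], ctr[501:1000, "y"],
                      "absence")
  expect_error(
    fit_ensemble(pres, abs, ps, families = "glm", retention_auc = 0.90,
                 reps = 4, seed = 10),
    "retention_auc")
  fit <- fit_ensemble(pres, abs, ps, families = c("glm", "rf"),
                      retention_auc = 0.5 - 0.1, reps = 4, seed = 10)
  for (l in fit$model$learners) {
    expect_gt(l$mean_auc, 0.4)
    expect_lt(l$mean_auc, 0.6)
  }
})

test_that("permutation importances are nonnegative and sum to 100", {
  ps <- make_predictor_stack(c(30, 30), 1000, 1, 1, seed = 7)
  spec <- species_spec("s", c(smooth1 = 2, dist1 = -1), intercept = -0.5)
  truth <- true_suitability(spec, ps)
  pres <- sample_transect_presences(truth, seed = 12, species = "s")
  abs <- generate_pseudo_absences(ps$layers[[1]], pres, "random_equal",
                                  seed = 13)
  fit <- fit_ensemble(pres, abs, ps, families = c("glm", "brt"),
                      retention_auc = 0.5, reps = 3, seed = 14)
  for (l in fit$model$learners) {
    expect_true(all(l$predictor_contributions >= 0))
    expect_equal(sum(l$predictor_contributions), 100, tolerance = 1e-6)
  }
})

test_that("stacking sums probabilities cell-wise with nodata propagation", {
  g <- raster_grid(matrix(0.5, 10, 10))
  maps <- lapply(1:7, function(i) suitability_map(g, paste0("s", i)))
  st <- stack_suitability(maps)
  expect_equal(unique(as.vector(st$grid$values)), 3.5)
  expect_equal(st$n_species, 7)
  expect_equal(st$species_label, "stacked")
  # single map: identity
  one <- stack_suitability(maps[1])
  expect_equal(one$grid$values, g$values)
  # nodata in any layer propagates
  nod <- matrix(FALSE, 10, 10); nod[3, 3] <- TRUE
  g2 <- raster_grid(matrix(0.5, 10, 10), nodata = nod)
  st2 <- stack_suitability(list(maps[[1]], suitability_map(g2, "s2")))
  expect_true(st2$grid$nodata[3, 3])
  # shape mismatch rejected
  g3 <- raster_grid(matrix(0.5, 9, 10))
  expect_error(stack_suitability(list(maps[[1]], suitability_map(g3, "s3"))),
               "compatible")
})
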