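# Ensemble habitat-suitability modelling: collinearity screening, geographic
# thinning, pseudo-absence generation, AUC-thresholded learner retention and
# AUC-weighted ensemble prediction, plus cell-wise stacking across species.

#' Rank-based AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney statistic; tied
#' scores contribute one half. This is the evaluation metric used both for
#' learner retention and for ensemble weighting.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 class labels (1 = presence).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores) # midranks: ties contribute 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Predictor collinearity screen
#'
#' Reports all pairwise Pearson correlations between predictor layers over
#' jointly valid cells and flags pairs whose |r| exceeds the threshold.
#' Layers are never dropped automatically; the report is advisory, matching
#' the common practice of screening predictors at |r| > 0.7 before fitting.
#'
#' @param predictors a `predictor_stack` with at least two layers.
#' @param threshold absolute correlation flag threshold.
#' @return data frame with columns `layer_a`, `layer_b`, `r`, `flagged`,
#'   `note`; attribute `"threshold"`. Pairs involving a constant layer have
#'   `r = NA` and an explanatory note.
#' @export
collinearity_screen <- function(predictors, threshold = 0.7) {
  nm <- predictors$names
  if (length(nm) < 2) stop("need at least two layers to screen")
  ok <- Reduce(`&`, lapply(predictors$layers, valid_mask))
  cols <- vapply(predictors$layers, function(g) g$values[ok],
                 numeric(sum(ok)))
  pairs <- utils::combn(nm, 2)
  res <- data.frame(layer_a = pairs[1, ], layer_b = pairs[2, ],
                    r = NA_real_, flagged = FALSE, note = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- cols[, pairs[1, i]]; b <- cols[, pairs[2, i]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      res$note[i] <- "undefined: constant layer"
    } else {
      res$r[i] <- stats::cor(a, b)
      res$flagged[i] <- abs(res$r[i]) > threshold
    }
  }
  attr(res, "threshold") <- threshold
  res
}

#' Geographic thinning of presence points
#'
#' Greedy seeded thinning: points are visited in a seeded random order and a
#' point is kept iff no previously kept point lies within `min_distance`.
#' The result therefore satisfies the minimum-distance property exactly.
#' Thinning reduces spatial sampling bias from clustered observations (for
#' example dung-pile records along a heavily used path).
#'
#' @param points a `presence_set`.
#' @param min_distance minimum pairwise distance (m); 0 returns the input
#'   unchanged.
#' @param seed integer seed controlling the visit order.
#' @return the thinned `presence_set`.
#' @export
thin_points <- function(points, min_distance, seed = 1) {
  if (min_distance < 0) stop("min_distance must be >= 0")
  n <- n_points(points)
  if (min_distance == 0 || n <= 1) return(points)
  ord <- with_seed(seed, sample.int(n))
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        all((points$x[keep] - points$x[i])^2 +
            (points$y[keep] - points$y[i])^2 >= min_distance^2)) {
      keep <- c(keep, i)
    }
  }
  keep <- sort(keep)
  presence_set(points$species, points$x[keep], points$y[keep],
               source_label = points$source_label)
}

#' Generate pseudo-absences
#'
#' Background points standing in for true absences: cells are drawn
#' uniformly without replacement from valid cells not containing a presence,
#' and returned as the cell centres.
#'
#' @param grid a `raster_grid` defining the study extent.
#' @param presences a `presence_set` whose cells are excluded.
#' @param strategy `"random"` (draw `n` points) or `"random_equal"` (one per
#'   presence).
#' @param n number of pseudo-absences (`random` strategy).
#' @param seed integer seed.
#' @return a `presence_set` with `source_label = "absence"`.
#' @export
generate_pseudo_absences <- function(grid, presences,
                                     strategy = c("random", "random_equal"),
                                     n = 1000, seed = 1) {
  strategy <- match.arg(strategy)
  if (strategy == "random_equal") n <- n_points(presences)
  if (n < 1) stop("need at least one pseudo-absence")
  ok <- valid_mask(grid)
  if (n_points(presences) > 0) {
    rc <- locate_cells(grid, presences$x, presences$y)
    rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
    ok[rc] <- FALSE
  }
  avail <- which(ok)
  if (n > length(avail)) {
    stop(sprintf("requested %d pseudo-absences but only %d cells available",
                 n, length(avail)))
  }
  cells <- with_seed(seed, sample(avail, n))
  rc <- arrayInd(cells, dim(grid$values))
  ctr <- cell_centers(grid, rc[, 1], rc[, 2])
  presence_set(presences$species, ctr[, "x"], ctr[, "y"],
               source_label = "absence")
}

# --- learner-family registry -----------------------------------------------
# Each family supplies fit(x, y, seed) -> model and predict(model, x) ->
# probability vector. The registry is extensible: pass extra families to
# fit_ensemble() via `registry`.

quadratic_features <- function(x) {
  as.matrix(cbind(x, setNames(x^2, paste0(names(x), "_sq"))))
}

#' Default learner-family registry
#'
#' Four probabilistic presence/absence learners: `glm` (logistic
#' regression), `brt` (boosted regression trees via xgboost), `rf`
#' (probability random forest via ranger) and `maxlike` (an exponential-
#' family model: lasso-regularised logistic regression on linear plus
#' quadratic features, in the spirit of maximum-entropy distribution
#' models).
#'
#' @return named list of families, each a list with `fit` and `predict`.
#' @export
default_learner_registry <- function() {
  list(
    glm = list(
      fit = function(x, y, seed) {
        d <- cbind(.y = y, x)
        suppressWarnings(stats::glm(.y ~ ., data = d,
                                    family = stats::binomial()))
      },
      predict = function(model, x) {
        as.numeric(stats::predict(model, newdata = x, type = "response"))
      }),
    brt = list(
      fit = function(x, y, seed) {
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 3,
                        eta = 0.1, min_child_weight = 5,
                        tree_method = "exact", nthread = 1, seed = seed),
          data = dtrain, nrounds = 60, verbose = 0)
      },
      predict = function(model, x) {
        as.numeric(stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x))))
      }),
    rf = list(
      fit = function(x, y, seed) {
        d <- cbind(.y = factor(y, levels = c(0, 1)), x)
        ranger::ranger(.y ~ ., data = d, probability = TRUE,
                       num.trees = 300, seed = seed, num.threads = 1)
      },
      predict = function(model, x) {
        as.numeric(stats::predict(model, data = x,
                                  num.threads = 1)$predictions[, "1"])
      }),
    maxlike = list(
      fit = function(x, y, seed) {
        xf <- quadratic_features(x)
        with_seed(seed,
          glmnet::cv.glmnet(xf, y, family = "binomial", alpha = 1,
                            nfolds = 5, standardize = TRUE))
      },
      predict = function(model, x) {
        as.numeric(stats::predict(model, newx = quadratic_features(x),
                                  s = "lambda.min", type = "response"))
      })
  )
}

extract_predictors <- function(predictors, ps) {
  g <- predictors$layers[[1]]
  rc <- locate_cells(g, ps$x, ps$y)
  if (anyNA(rc)) stop("points fall outside the predictor grid")
  out <- as.data.frame(lapply(predictors$layers, function(l) l$values[rc]))
  names(out) <- predictors$names
  out
}

stratified_split <- function(y, holdout_fraction, seed) {
  with_seed(seed, {
    test <- logical(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_test <- max(1L, round(holdout_fraction * length(idx)))
      test[sample(idx, n_test)] <- TRUE
    }
    test
  })
}

#' Fit an AUC-weighted ensemble suitability model
#'
#' For each learner family, `reps` stratified random holdout splits are
#' evaluated (training on `1 - holdout_fraction` of presences and absences,
#' scoring AUC on the rest). Families whose mean holdout AUC reaches
#' `retention_auc` are retained, refitted on all data and combined into a
#' per-cell ensemble prediction weighted by mean AUC. Per-predictor
#' contributions are estimated by permutation importance (drop in full-data
#' AUC when one predictor's values are permuted), floored at zero and
#' normalised to sum 100.
#'
#' @param presences,absences `presence_set` objects (absences typically from
#'   [generate_pseudo_absences()]).
#' @param predictors a `predictor_stack`.
#' @param families character vector of registry family names.
#' @param retention_auc retention threshold on mean holdout AUC (default
#'   0.90).
#' @param holdout_fraction held-out fraction per repetition (default 0.30).
#' @param reps number of holdout repetitions (default 10).
#' @param seed integer seed; rep splits and permutations derive from it.
#' @param registry learner registry, see [default_learner_registry()].
#' @param weighting `"auc"` (weights proportional to mean holdout AUC) or
#'   `"equal"`.
#' @return list with `model` (class `ensemble_model`: per-family rep AUCs,
#'   mean AUC, retention flags, contributions, weights) and `map` (a
#'   `suitability_map` whose grid holds the ensemble prediction in \[0, 1\]).
#' @export
fit_ensemble <- function(presences, absences, predictors,
                         families = c("glm", "brt", "rf", "maxlike"),
                         retention_auc = 0.90, holdout_fraction = 0.30,
                         reps = 10, seed = 1,
                         registry = default_learner_registry(),
                         weighting = c("auc", "equal")) {
  weighting <- match.arg(weighting)
  if (length(families) == 0) stop("families must be nonempty")
  missing <- setdiff(families, names(registry))
  if (length(missing) > 0) {
    stop(sprintf("unknown learner families: %s", paste(missing, collapse = ", ")))
  }
  xp <- extract_predictors(predictors, presences)
  xa <- extract_predictors(predictors, absences)
  x <- rbind(xp, xa)
  y <- c(rep(1L, nrow(xp)), rep(0L, nrow(xa)))
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least two presences and two absences")
  }

  learners <- list()
  for (fam in families) {
    fml <- registry[[fam]]
    rep_aucs <- numeric(reps)
    for (r in seq_len(reps)) {
      split_seed <- derive_seed(seed, paste0("split-", fam, "-", r))
      test <- stratified_split(y, holdout_fraction, split_seed)
      model <- fml$fit(x[!test, , drop = FALSE], y[!test], split_seed)
      rep_aucs[r] <- auc(fml$predict(model, x[test, , drop = FALSE]), y[test])
    }
    mean_auc <- mean(rep_aucs)
    learners[[fam]] <- list(family = fam, rep_aucs = rep_aucs,
                            mean_auc = mean_auc,
                            retained = mean_auc >= retention_auc)
  }
  retained <- names(Filter(function(l) l$retained, learners))
  if (length(retained) == 0) {
    stop(sprintf(paste0(
      "no learner family reached the retention AUC of %.2f ",
      "(best mean AUC %.3f); lower retention_auc to keep an ensemble"),
      retention_auc, max(vapply(learners, `[[`, 0, "mean_auc"))))
  }

  # refit on all data; permutation importance on the full-data predictions
  full_models <- list()
  for (fam in families) {
    fit_seed <- derive_seed(seed, paste0("full-", fam))
    full_models[[fam]] <- registry[[fam]]$fit(x, y, fit_seed)
    base_auc <- auc(registry[[fam]]$predict(full_models[[fam]], x), y)
    drops <- numeric(ncol(x)); names(drops) <- names(x)
    for (p in names(x)) {
      perm <- with_seed(derive_seed(seed, paste0("perm-", fam, "-", p)),
                        sample.int(nrow(x)))
      xperm <- x
      xperm[[p]] <- x[[p]][perm]
      drops[p] <- max(0, base_auc -
                        auc(registry[[fam]]$predict(full_models[[fam]], xperm), y))
    }
    contrib <- if (sum(drops) > 0) 100 * drops / sum(drops) else
      rep(100 / length(drops), length(drops))
    names(contrib) <- names(x)
    learners[[fam]]$predictor_contributions <- contrib
  }

  mean_aucs <- vapply(learners[retained], `[[`, 0, "mean_auc")
  w <- if (weighting == "auc") mean_aucs / sum(mean_aucs) else
    rep(1 / length(retained), length(retained))
  names(w) <- retained

  # predict over all valid cells
  g <- predictors$layers[[1]]
  ok <- Reduce(`&`, lapply(predictors$layers, valid_mask))
  newdata <- as.data.frame(lapply(predictors$layers,
                                  function(l) l$values[ok]))
  names(newdata) <- predictors$names
  pred <- rep(0, sum(ok))
  for (fam in retained) {
    pred <- pred + w[[fam]] * registry[[fam]]$predict(full_models[[fam]],
                                                      newdata)
  }
  pred <- pmin(1, pmax(0, pred))
  out <- g
  out$values[] <- 0
  out$values[ok] <- pred
  out$nodata <- out$nodata | !ok

  model <- structure(
    list(species = presences$species, learners = learners,
         retained = retained, weights = w, retention_auc = retention_auc,
         holdout_fraction = holdout_fraction, reps = reps,
         weighting = weighting),
    class = "ensemble_model")
  list(model = model,
       map = suitability_map(out, species_label = presences$species))
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %s (%d families, %d retained)\n",
              x$species, length(x$learners), length(x$retained)))
  for (l in x$learners) {
    cat(sprintf("  %-8s mean AUC %.3f %s\n", l$family, l$mean_auc,
                if (l$retained) sprintf("[retained, w=%.2f]",
                                        x$weights[[l$family]]) else ""))
  }
  invisible(x)
}

#' Learner report table
#'
#' One row per learner family: mean holdout AUC, retention flag and
#' per-predictor percentage contributions.
#'
#' @param model an `ensemble_model`.
#' @return data frame.
#' @export
learner_report <- function(model) {
  rows <- lapply(model$learners, function(l) {
    contrib <- as.list(l$predictor_contributions)
    names(contrib) <- paste0("contrib_", names(contrib))
    cbind(data.frame(species = model$species, family = l$family,
                     mean_auc = l$mean_auc, retained = l$retained),
          as.data.frame(contrib))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Suitability maps
#'
#' A raster of habitat suitability: per-species maps live in \[0, 1\];
#' stacked multi-species maps live in \[0, S\] for S species.
#'
#' @param grid a `raster_grid`.
#' @param species_label species name, or `"stacked"`.
#' @param n_species number of species summed into the map (1 for a
#'   single-species map).
#' @return an object of class `suitability_map`.
#' @export
suitability_map <- function(grid, species_label, n_species = 1) {
  v <- grid$values[valid_mask(grid)]
  if (length(v) > 0 && (min(v) < -1e-9 || max(v) > n_species + 1e-9)) {
    stop(sprintf("suitability values must lie in [0, %d]", n_species))
  }
  structure(list(grid = grid, species_label = species_label,
                 n_species = n_species),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("suitability_map: %s (S = %d)\n", x$species_label, x$n_species))
  print(x$grid)
  invisible(x)
}

#' Stack single-species suitability maps
#'
#' The multi-species habitat index: a cell-wise sum of the per-species
#' suitability probabilities. Cells that are nodata in any input are nodata
#' in the stack.
#'
#' @param maps list of `suitability_map` objects, each with values in
#'   \[0, 1\].
#' @return a `suitability_map` with `species_label = "stacked"` and values
#'   in \[0, S\].
#' @export
stack_suitability <- function(maps) {
  if (length(maps) < 1) stop("need at least one map to stack")
  g0 <- maps[[1]]$grid
  total <- matrix(0, nrow(g0$values), ncol(g0$values))
  nodata <- matrix(FALSE, nrow(g0$values), ncol(g0$values))
  for (m in maps) {
    stop_if_incompatible(g0, m$grid, "suitability maps")
    if (m$n_species != 1) stop("stack inputs must be single-species maps")
    total <- total + m$grid$values
    nodata <- nodata | !valid_mask(m$grid)
  }
  total[nodata] <- 0
  out <- raster_grid(total, origin = g0$origin, cell_size = g0$cell_size,
                     nodata = nodata, crs_label = g0$crs_label)
  suitability_map(out, species_label = "stacked", n_species = length(maps))
}
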