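# Pipeline orchestration: one seeded config drives simulation, model
# fitting, resistance scaling, connectivity and comparison, writing every
# product plus a manifest to a run directory.

#' Derive a stage seed from the run seed
#'
#' One global seed is fanned out to per-stage child seeds by hashing the
#' stage label (a small polynomial string hash mod 2^31 - 1), so a change
#' in one stage's draw count never shifts another stage's stream.
#'
#' @param seed integer run seed.
#' @param label stage label.
#' @return integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, label) {
  mod <- 2147483647
  h <- as.double(seed %% mod)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% mod
  }
  as.integer(h) + 1L
}

#' Default run configuration
#'
#' All tunables of a full synthetic-landscape run in one list, serialisable
#' losslessly to YAML. Fields mirror the stage parameters: grid shape and
#' cell size, species count, learner families and retention threshold,
#' holdout settings, thinning distance, pseudo-absence strategy, resistance
#' scalings, connectivity methods and corridor slice.
#'
#' @param seed global run seed.
#' @param ... overrides for any default field.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(seed = 42, ...) {
  cfg <- list(
    seed = seed,
    shape = c(60, 60),
    cell_size = 1000,
    n_smooth_fields = 2,
    n_distance_fields = 2,
    smooth_sd = 5,
    n_species = 7,
    generalist = TRUE,
    coef_sd = 1.5,
    intercept = -1,
    detection_scale = 1,
    transect_spacing = 1000,
    terminal_frac = 0.05,
    families = c("glm", "brt", "rf", "maxlike"),
    retention_auc = 0.90,
    holdout_fraction = 0.30,
    reps = 10,
    thinning_distance = 1000,
    pseudo_absence_strategy = "random_equal",
    pseudo_absence_n = 1000,
    ensemble_weighting = "auc",
    scalings = c("linear", "nonlinear"),
    methods = c("least_cost", "circuit"),
    slice_fraction = 0.10,
    connectivity = 8,
    overlap_convention = "jaccard")
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = c("run_config", "list"))
}

#' Read / write a run configuration as YAML
#'
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  # restore numeric types YAML may have read as integer
  for (nm in names(cfg)) {
    if (nm %in% names(base) && is.numeric(base[[nm]])) {
      cfg[[nm]] <- as.numeric(cfg[[nm]])
    }
  }
  out <- base
  out[names(cfg)] <- cfg
  structure(out, class = c("run_config", "list"))
}

#' Build the synthetic species assemblage for a run
#'
#' Species coefficients are drawn i.i.d. normal with sd `coef_sd` on the
#' log-odds scale; when `generalist = TRUE` the last species is the
#' niche-centroid generalist whose coefficients are the mean of the
#' others' (its habitat preference averages the assemblage, the pattern a
#' proxy species is expected to show).
#'
#' @param predictors a `predictor_stack`.
#' @param n_species number of species.
#' @param seed integer seed.
#' @param coef_sd coefficient scale (log-odds per sd of predictor).
#' @param intercept shared log-odds intercept.
#' @param generalist whether the last species is the niche centroid.
#' @return named list of `species_spec`.
#' @export
make_species_assemblage <- function(predictors, n_species = 7, seed = 1,
                                    coef_sd = 1.5, intercept = -1,
                                    generalist = TRUE) {
  if (n_species < 2) stop("need at least two species")
  p <- length(predictors$names)
  n_spec <- if (generalist) n_species - 1L else n_species
  specs <- with_seed(seed, {
    lapply(seq_len(n_spec), function(i) {
      co <- stats::rnorm(p, sd = coef_sd)
      names(co) <- predictors$names
      species_spec(sprintf("species%02d", i), co, intercept = intercept)
    })
  })
  if (generalist) {
    co <- colMeans(do.call(rbind, lapply(specs, `[[`, "coefficients")))
    specs <- c(specs, list(species_spec("generalist", co,
                                        intercept = intercept)))
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

fit_species_sdm <- function(sp_name, truth, predictors, cfg) {
  pres <- sample_transect_presences(
    truth, transect_spacing = cfg$transect_spacing,
    detection_scale = cfg$detection_scale,
    seed = derive_seed(cfg$seed, paste0("transect-", sp_name)),
    species = sp_name)
  pres <- thin_points(pres, cfg$thinning_distance,
                      seed = derive_seed(cfg$seed, paste0("thin-", sp_name)))
  if (n_points(pres) < 10) {
    stop(sprintf("species %s: too few presences (%d) to fit a model",
                 sp_name, n_points(pres)))
  }
  abs <- generate_pseudo_absences(
    predictors$layers[[1]], pres, strategy = cfg$pseudo_absence_strategy,
    n = cfg$pseudo_absence_n,
    seed = derive_seed(cfg$seed, paste0("absence-", sp_name)))
  fit_ensemble(pres, abs, predictors, families = cfg$families,
               retention_auc = cfg$retention_auc,
               holdout_fraction = cfg$holdout_fraction, reps = cfg$reps,
               seed = derive_seed(cfg$seed, paste0("fit-", sp_name)),
               weighting = cfg$ensemble_weighting)
}

#' Run the full multi-species corridor pipeline
#'
#' Simulates the landscape and assemblage, fits per-species ensembles,
#' stacks them, derives linear and non-linear resistance surfaces, runs
#' least-cost and circuit connectivity for every species and the stacked
#' map, and writes comparison matrices, proxy rankings, all rasters and a
#' JSON manifest to `out_dir`.
#'
#' Exact stages (simulation, transforms, graph build) are bit-reproducible
#' given the config; solver stages are reproducible to tight numerical
#' tolerance.
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (created if missing); `NULL` to skip all
#'   file output and return results only.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory products: `predictors`,
#'   `terminals`, `specs`, `models`, `suitability` (incl. `"stacked"`),
#'   `connectivity[[scaling]][[label]]`, `correlations`, `overlaps`,
#'   `rankings`, `manifest`.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(nm, expr) {
    say("[%s] ...", nm)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", nm,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  predictors <- stage("simulate", make_predictor_stack(
    cfg$shape, cell_size = cfg$cell_size,
    n_smooth_fields = cfg$n_smooth_fields,
    n_distance_fields = cfg$n_distance_fields,
    seed = derive_seed(cfg$seed, "predictors"),
    smooth_sd = cfg$smooth_sd))
  grid <- predictors$layers[[1]]
  terminals <- make_terminals(grid, frac = cfg$terminal_frac)
  specs <- make_species_assemblage(predictors, cfg$n_species,
                                   seed = derive_seed(cfg$seed, "species"),
                                   coef_sd = cfg$coef_sd,
                                   intercept = cfg$intercept,
                                   generalist = cfg$generalist)

  models <- list(); suit <- list()
  for (sp in names(specs)) {
    res <- stage(paste0("sdm-", sp), {
      truth <- true_suitability(specs[[sp]], predictors)
      fit_species_sdm(sp, truth, predictors, cfg)
    })
    models[[sp]] <- res$model
    suit[[sp]] <- res$map
  }
  suit$stacked <- stack_suitability(suit[names(specs)])

  conn <- list(); lcp <- list(); reff <- list()
  for (scaling in cfg$scalings) {
    conn[[scaling]] <- list()
    for (lb in names(suit)) {
      hs <- if (lb == "stacked") normalize_stacked(suit$stacked) else suit[[lb]]
      rs <- if (scaling == "linear") linear_resistance(hs) else
        nonlinear_resistance(hs)
      conn[[scaling]][[lb]] <- stage(
        paste0("connectivity-", scaling, "-", lb),
        run_species_connectivity(rs, terminals[[1]], terminals[[2]],
                                 slice_fraction = cfg$slice_fraction,
                                 connectivity = cfg$connectivity,
                                 methods = cfg$methods))
      lcp[[paste(scaling, lb, sep = ".")]] <-
        conn[[scaling]][[lb]]$corridor$lcp_cost
      reff[[paste(scaling, lb, sep = ".")]] <-
        conn[[scaling]][[lb]]$circuit$effective_resistance
    }
  }

  correlations <- list(); overlaps <- list(); rankings <- list()
  for (scaling in cfg$scalings) {
    prods <- list(
      suitability = lapply(suit, function(s) s$grid),
      current = if ("circuit" %in% cfg$methods)
        lapply(conn[[scaling]], function(x) x$circuit$current),
      nlcc = if ("least_cost" %in% cfg$methods)
        lapply(conn[[scaling]], function(x) x$corridor$nlcc))
    for (prod in names(Filter(Negate(is.null), prods))) {
      m <- comparison_matrix(prods[[prod]], "pearson_r")
      correlations[[paste(scaling, prod, sep = ".")]] <- m
      rankings[[paste(scaling, prod, sep = ".")]] <- proxy_ranking(m)
    }
    if ("least_cost" %in% cfg$methods) {
      masks <- lapply(conn[[scaling]], function(x) x$corridor$mask)
      m <- comparison_matrix(masks, "percent_overlap",
                             convention = cfg$overlap_convention)
      overlaps[[scaling]] <- m
      rankings[[paste(scaling, "overlap", sep = ".")]] <- proxy_ranking(m)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("corridors")),
    config = unclass(cfg),
    species = names(specs),
    n_presences = NULL,
    lcp_cost = lcp,
    effective_resistance = reff,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(predictors = predictors, terminals = terminals,
                 specs = specs, models = models, suitability = suit,
                 connectivity = conn, correlations = correlations,
                 overlaps = overlaps, rankings = rankings,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    stage("write", write_run_outputs(result, cfg, out_dir))
  }
  say("pipeline finished in %.1f s", manifest$elapsed_s)
  invisible(result)
}

write_run_outputs <- function(result, cfg, out_dir) {
  write_stack_dir(result$predictors, file.path(out_dir, "predictors"))
  grid <- result$predictors$layers[[1]]
  write_terminal(result$terminals[[1]], grid,
                 file.path(out_dir, "terminal_a.asc"))
  write_terminal(result$terminals[[2]], grid,
                 file.path(out_dir, "terminal_b.asc"))
  sdir <- file.path(out_dir, "suitability")
  dir.create(sdir, showWarnings = FALSE)
  for (lb in names(result$suitability)) {
    write_ascii_grid(result$suitability[[lb]]$grid,
                     file.path(sdir, paste0(lb, ".asc")))
  }
  reports <- do.call(rbind, lapply(result$models, learner_report))
  utils::write.csv(reports, file.path(out_dir, "learner_report.csv"),
                   row.names = FALSE)
  for (scaling in names(result$connectivity)) {
    cdir <- file.path(out_dir, paste0("connectivity_", scaling))
    dir.create(cdir, showWarnings = FALSE)
    for (lb in names(result$connectivity[[scaling]])) {
      prod <- result$connectivity[[scaling]][[lb]]
      if (!is.null(prod$corridor)) {
        write_ascii_grid(prod$corridor$nlcc,
                         file.path(cdir, paste0(lb, "_nlcc.asc")))
        mg <- raster_grid(prod$corridor$mask * 1, origin = grid$origin,
                          cell_size = grid$cell_size)
        write_ascii_grid(mg, file.path(cdir, paste0(lb, "_mask.asc")))
      }
      if (!is.null(prod$circuit) && prod$circuit$connected) {
        write_ascii_grid(prod$circuit$current,
                         file.path(cdir, paste0(lb, "_current.asc")))
        write_ascii_grid(prod$circuit$voltage,
                         file.path(cdir, paste0(lb, "_voltage.asc")))
      }
    }
  }
  for (nm in names(result$correlations)) {
    write_comparison_csv(result$correlations[[nm]],
                         file.path(out_dir, paste0("correlation_", nm, ".csv")))
  }
  for (nm in names(result$overlaps)) {
    write_comparison_csv(result$overlaps[[nm]],
                         file.path(out_dir, paste0("overlap_", nm, ".csv")))
  }
  for (nm in names(result$rankings)) {
    utils::write.csv(result$rankings[[nm]],
                     file.path(out_dir, paste0("ranking_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
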