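# Shared Monte-Carlo batch: 20 seeded 7-species assemblages on 40 x 40
# landscapes, each run yielding proxy rankings from circuit-current
# correlations under both resistance scalings. Computed once per session
# and cached (several tests consume the same runs).
.assemblage_cache <- new.env(parent = emptyenv())

assemblage_batch <- function(n_runs = 20, shape = 40) {
  key <- sprintf("runs_%d_%d", n_runs, shape)
  if (!is.null(.assemblage_cache[[key]])) return(.assemblage_cache[[key]])
  runs <- lapply(seq_len(n_runs), function(s) {
    ps <- make_predictor_stack(c(shape, shape), 1000, 2, 2,
                               seed = derive_seed(s, "pred"))
    specs <- make_species_assemblage(ps, 7, seed = derive_seed(s, "spp"),
                                     coef_sd = 1.5, intercept = -1,
                                     generalist = TRUE)
    tt <- make_terminals(ps$layers[[1]], frac = 0.05)
    out <- list()
    for (scal in c("linear", "nonlinear")) {
      cur <- list()
      for (nm in names(specs)) {
        hs <- suitability_map(true_suitability(specs[[nm]], ps), nm)
        rs <- if (scal == "linear") linear_resistance(hs) else
          nonlinear_resistance(hs)
        cur[[nm]] <- circuit_solve(build_graph(rs, tt[[1]], tt[[2]]))$current
      }
      out[[scal]] <- proxy_ranking(comparison_matrix(cur, "pearson_r"))
    }
    out
  })
  .assemblage_cache[[key]] <- runs
  runs
}

rank_agreement <- function(a, b) {
  stats::cor(match(a$label, b$label), seq_len(nrow(a)), method = "spearman")
}
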