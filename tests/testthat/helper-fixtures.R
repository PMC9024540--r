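# Shared fixtures. The "clean world" is a peaked two-driver virtual species
# on a 120x120 synthetic climate (the package's reference study conditions);
# it is expensive to fit, so it is built once per test run and cached.

make_stack <- function(..., cellsize = 0.1) {
  layers <- list(...)
  raster_stack(layers, xll = 0, yll = 0, cellsize = cellsize)
}

clean_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- climate_spec(5, c(120, 120), spatial_range = 8,
                           nodata_fraction = 0.05, seed = 42)
      stk <- generate_climate(spec)
      sp <- virtual_species(c("env_1", "env_3"), c(0.5, -0.5), c(0.25, 0.25))
      suit <- true_suitability(stk, sp)
      occ <- sample_occurrences(suit, 300, seed = 7)
      pa <- sample_pseudo_absences(stk, occ, n = 2000, seed = 8)
      ds <- modeling_dataset(stk, occ, pa)
      suite <- fit_suite(ds, reps = 3, seed = 11)
      cache <<- list(spec = spec, stack = stk, species = sp, suit = suit,
                     occ = occ, pa = pa, dataset = ds, suite = suite)
    }
    cache
  }
})

clean_ensembles <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- clean_world()
      cache <<- lapply(c(committee = "committee", weighted = "weighted"),
                       function(m) evaluate_ensemble(
                         build_ensemble(w$suite, method = m), w$dataset))
    }
    cache
  }
})

clean_importance <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- clean_world()
      set.seed(19)
      rows <- sample(nrow(w$dataset$X), 600)
      cache <<- importance_table(w$suite, w$dataset$X[rows, ], n_perm = 2,
                                 seed = 5)
    }
    cache
  }
})

# A fake fitted model with constant prediction p0 (a GLM with an intercept-only
# coefficient vector), for exercising ensemble arithmetic with known scores.
const_model <- function(p0, tss, threshold = 0.5, predictors = "x1") {
  d <- data.frame(x1 = c(-1, -0.5, 0.5, 1), .y = c(0, 0, 1, 1))
  fit <- suppressWarnings(stats::glm(.y ~ x1, data = d, family = binomial()))
  fit$coefficients[] <- c(stats::qlogis(p0), 0)
  structure(list(algorithm = "GLM", repetition = 1L, predictors = predictors,
                 failed = FALSE, reason = NULL,
                 eval = structure(list(auc = 1, tss = tss,
                                       tss_threshold = threshold,
                                       sensitivity = 1, specificity = tss),
                                  class = "evaluation_result"),
                 object = list(fit = fit),
                 train_idx = 1:2, val_idx = 3:4),
            class = "sdm_model")
}
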