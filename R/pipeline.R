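#' Build and validate a run configuration
#'
#' All thresholds default to the conventional published values: correlation
#' cutoff 0.75, TSS gate 0.8, 80/20 split x 3 repetitions, 10,000
#' pseudo-absences, 100 x 100 niche grid, 99 permutations.
#'
#' @param occurrences path to an occurrence CSV (`species,lon,lat`).
#' @param current path to the current-climate layer directory (see
#'   [write_stack()]).
#' @param scenarios named character vector/list of future layer directories.
#' @param outdir output directory for the run.
#' @param correlation_threshold collinearity cutoff on |r| (default 0.75).
#' @param priority optional predictor priority order for the filter.
#' @param min_dist_km spatial thinning distance (default 0: one per cell).
#' @param pseudo_absences background size (default 10000).
#' @param train_frac,reps split fraction and repetitions (0.8, 3).
#' @param tss_gate ensemble membership gate (default 0.8).
#' @param ensemble_methods "committee", "weighted" or both (default both).
#' @param niche_R niche grid resolution (default 100).
#' @param perm_reps permutations for the niche tests (default 99).
#' @param importance_perms permutations per importance estimate (default 3).
#' @param bg_max background sample cap for PCA-env (default 10000).
#' @param niche_occ_max cap on predicted-presence cells used as each
#'   period's niche occurrences (default 500).
#' @param seed global seed; every stage derives sub-seeds from it.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(occurrences, current, scenarios, outdir,
                       correlation_threshold = 0.75, priority = NULL,
                       min_dist_km = 0, pseudo_absences = 10000,
                       train_frac = 0.8, reps = 3, tss_gate = 0.8,
                       ensemble_methods = c("committee", "weighted"),
                       niche_R = 100, perm_reps = 99, importance_perms = 3,
                       bg_max = 10000, niche_occ_max = 500, seed = 1) {
  cfg <- list(occurrences = occurrences, current = current,
              scenarios = as.list(scenarios), outdir = outdir,
              correlation_threshold = correlation_threshold,
              priority = priority, min_dist_km = min_dist_km,
              pseudo_absences = pseudo_absences, train_frac = train_frac,
              reps = reps, tss_gate = tss_gate,
              ensemble_methods = match.arg(ensemble_methods,
                                           c("committee", "weighted"),
                                           several.ok = TRUE),
              niche_R = niche_R, perm_reps = perm_reps,
              importance_perms = importance_perms, bg_max = bg_max,
              niche_occ_max = niche_occ_max, seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  if (is.null(names(cfg$scenarios)) || any(names(cfg$scenarios) == ""))
    stopf("scenarios must be a named list of layer directories")
  if (cfg$correlation_threshold <= 0 || cfg$correlation_threshold > 1)
    stopf("correlation_threshold must be in (0, 1]")
  if (cfg$tss_gate < -1 || cfg$tss_gate > 1) stopf("tss_gate must be in [-1, 1]")
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1) stopf("train_frac in (0,1)")
  if (cfg$reps < 1) stopf("reps must be >= 1")
  if (cfg$pseudo_absences < 1) stopf("pseudo_absences must be >= 1")
  if (cfg$niche_R < 10) stopf("niche_R must be >= 10")
  if (cfg$perm_reps < 19) stopf("perm_reps must be >= 19")
  invisible(cfg)
}

#' Read a run configuration from YAML
#' @param path YAML file with the [run_config()] fields.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Thin -> correlation filter -> pseudo-absences -> nine-algorithm suite ->
#' TSS-gated ensembles -> projection per scenario -> range change per
#' scenario -> PCA-env niche dynamics per scenario. Every artifact is
#' written under `outdir` as open text formats (CSV/JSON/ASCII grid) plus a
#' manifest with the config and seed, so identical config + seed reproduces
#' identical statistics files.
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @return invisibly, a list with the in-memory results (`report`, `suite`,
#'   `ensembles`, `range_change`, `niche`, `outdir`).
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  occ <- stage("read_occurrences", read_occurrences(cfg$occurrences))
  current <- stage("read_stack", read_stack(cfg$current))
  futures <- lapply(cfg$scenarios, function(p) stage("read_stack", read_stack(p)))

  occ <- stage("thin", thin_occurrences(occ, current, cfg$min_dist_km))
  write_occurrences(occ, file.path(cfg$outdir, "occurrences_thinned.csv"))

  report <- stage("filter", {
    cm <- correlation_matrix(current)
    select_uncorrelated(cm, threshold = cfg$correlation_threshold,
                        priority = cfg$priority)
  })
  write_correlation_report(report, cfg$outdir)
  current_r <- subset_stack(current, report$retained)
  futures_r <- lapply(futures, subset_stack, keep = report$retained)

  pa <- stage("pseudo_absences",
              sample_pseudo_absences(current_r, occ, n = cfg$pseudo_absences,
                                     seed = sub_seed(cfg$seed, 2)))
  dataset <- stage("dataset", modeling_dataset(current_r, occ, pa))
  suite <- stage("fit_suite",
                 fit_suite(dataset, reps = cfg$reps,
                           train_frac = cfg$train_frac,
                           seed = sub_seed(cfg$seed, 3)))
  utils::write.csv(suite_scores(suite),
                   file.path(cfg$outdir, "model_evaluation.csv"),
                   row.names = FALSE)

  imp <- stage("importance",
               importance_table(suite, dataset$X,
                                n_perm = cfg$importance_perms,
                                seed = sub_seed(cfg$seed, 4)))
  utils::write.csv(round(imp, 3),
                   file.path(cfg$outdir, "variable_importance.csv"))

  ensembles <- list()
  projections <- list()
  rc_stats <- list()
  for (method in cfg$ensemble_methods) {
    ens <- stage("ensemble", build_ensemble(suite, gate = cfg$tss_gate,
                                            method = method))
    ens <- stage("ensemble_eval", evaluate_ensemble(ens, dataset))
    ensembles[[method]] <- ens
    cur_proj <- stage("project", project_ensemble(ens, current_r, "current"))
    projections[[paste0("current|", method)]] <- cur_proj
    write_stack(cur_proj, file.path(cfg$outdir, paste0("suitability_current_",
                                                       method)))
    cut <- ens$eval$tss_threshold * 1000
    cur_bin <- binarize(cur_proj, cut)
    for (sc in names(futures_r)) {
      fut_proj <- stage("project", project_ensemble(ens, futures_r[[sc]], sc))
      projections[[paste0(sc, "|", method)]] <- fut_proj
      write_stack(fut_proj, file.path(cfg$outdir,
                                      paste0("suitability_", sc, "_", method)))
      rc <- stage("range_change",
                  range_change_stats(cur_bin, binarize(fut_proj, cut)))
      rc_stats[[paste0(sc, "|", method)]] <- rc
      write_stack(rc$change_map,
                  file.path(cfg$outdir, paste0("change_map_", sc, "_", method)))
    }
  }
  rc_table <- range_change_table(rc_stats)
  utils::write.csv(rc_table, file.path(cfg$outdir, "range_change.csv"),
                   row.names = FALSE)

  # Niche dynamics: each period's "occurrences" are its predicted-presence
  # cells (first ensemble method), its background all valid cells; both
  # subsampled with derived seeds.
  ens0 <- ensembles[[1L]]
  cut0 <- ens0$eval$tss_threshold * 1000
  niche_rows <- list()
  niche_results <- list()
  env_table <- function(stk, cells)
    as.data.frame(lapply(stk$layers, function(m) m[cells]), optional = TRUE)
  cur_proj0 <- projections[[paste0("current|", names(ensembles)[1L])]]
  for (sc in names(futures_r)) {
    res <- stage(paste0("niche_", sc), {
      fut_proj0 <- projections[[paste0(sc, "|", names(ensembles)[1L])]]
      valid <- which(stack_mask(current_r))
      bg_cells <- with_seed(sub_seed(cfg$seed, 20),
        if (length(valid) > cfg$bg_max) sample(valid, cfg$bg_max) else valid)
      pres_cur <- which(!is.na(cur_proj0$layers[[1L]]) &
                          cur_proj0$layers[[1L]] >= cut0)
      pres_fut <- which(!is.na(fut_proj0$layers[[1L]]) &
                          fut_proj0$layers[[1L]] >= cut0)
      if (length(pres_cur) < 5L || length(pres_fut) < 5L)
        stopf("fewer than 5 predicted-presence cells in a period")
      pres_cur <- with_seed(sub_seed(cfg$seed, 21),
        if (length(pres_cur) > cfg$niche_occ_max)
          sample(pres_cur, cfg$niche_occ_max) else pres_cur)
      pres_fut <- with_seed(sub_seed(cfg$seed, 22),
        if (length(pres_fut) > cfg$niche_occ_max)
          sample(pres_fut, cfg$niche_occ_max) else pres_fut)
      compare_niches(env_table(current_r, bg_cells),
                     env_table(futures_r[[sc]], bg_cells),
                     env_table(current_r, pres_cur),
                     env_table(futures_r[[sc]], pres_fut),
                     R = cfg$niche_R, reps = cfg$perm_reps,
                     seed = sub_seed(cfg$seed, 30 + match(sc, names(futures_r))))
    })
    niche_results[[sc]] <- res
    niche_rows[[sc]] <- data.frame(
      Pair = paste0("current vs. ", sc),
      PC1_pct = round(res$pca$explained_pct[1], 2),
      PC2_pct = round(res$pca$explained_pct[2], 2),
      Overlap_D = round(res$D, 4),
      Equivalency_p = round(res$equivalency$p_value, 5),
      Similarity_p = round(res$similarity$p_value, 5))
  }
  niche_table <- do.call(rbind, niche_rows)
  rownames(niche_table) <- NULL
  utils::write.csv(niche_table, file.path(cfg$outdir, "niche_overlap.csv"),
                   row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ensdm")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("priority"))],
    retained_predictors = as.list(report$retained),
    n_models = length(suite$models),
    ensemble_eval = lapply(ensembles, function(e)
      list(auc = e$eval$auc, tss = e$eval$tss,
           tss_threshold = e$eval$tss_threshold,
           members = length(e$members))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(report = report, suite = suite, ensembles = ensembles,
                 importance = imp, range_change = rc_table,
                 niche = niche_table, niche_results = niche_results,
                 outdir = cfg$outdir))
}
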