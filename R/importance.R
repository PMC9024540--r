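#' Permutation variable importance (one minus correlation)
#'
#' Permutes one predictor column, re-predicts, and reports
#' `mean over permutations of max(0, 1 - Pearson r(original, permuted))`.
#' 0 means the model's predictions are unchanged by scrambling the variable
#' (it is irrelevant); values near 1 mean the predictions are destroyed.
#'
#' @param model an `sdm_model`.
#' @param data data.frame of predictor values (typically `dataset$X`).
#' @param variable predictor name to permute.
#' @param n_perm number of permutations averaged (default 3).
#' @param seed RNG seed (per-permutation sub-seeds are derived).
#' @return importance in [0, 1].
#' @export
permutation_importance <- function(model, data, variable, n_perm = 3, seed = 1) {
  if (!variable %in% names(data)) stopf("variable '%s' not in data", variable)
  orig <- predict(model, data)
  if (stats::sd(orig) == 0) {
    warnf("constant original predictions; importance defined as 0")
    return(0)
  }
  vals <- vapply(seq_len(n_perm), function(i) {
    perm <- data
    perm[[variable]] <- with_seed(sub_seed(seed, i), sample(perm[[variable]]))
    pp <- predict(model, perm)
    r <- if (stats::sd(pp) == 0) 0 else stats::cor(orig, pp)
    max(0, 1 - r)
  }, numeric(1))
  mean(vals)
}

#' Importance table across a fitted suite
#'
#' Per (algorithm, variable): permutation importance averaged over the
#' algorithm's repetitions; plus a `Mean` column averaging across
#' algorithms — the layout of the familiar per-algorithm importance tables
#' (rows = variables, columns = algorithms + Mean).
#'
#' @param suite an `sdm_suite`.
#' @param data predictor data.frame (typically the modeling dataset's `X`).
#' @param n_perm permutations per (model, variable).
#' @param seed RNG seed.
#' @return data.frame, rows = variables, columns = algorithms + `Mean`.
#' @export
importance_table <- function(suite, data, n_perm = 3, seed = 1) {
  vars <- names(data)
  algos <- suite$algorithms
  tab <- matrix(NA_real_, length(vars), length(algos),
                dimnames = list(vars, algos))
  for (a in algos) {
    ms <- Filter(function(m) m$algorithm == a && !m$failed, suite$models)
    if (length(ms) == 0L) next
    for (v in vars) {
      vals <- vapply(seq_along(ms), function(k)
        permutation_importance(ms[[k]], data, v, n_perm = n_perm,
                               seed = sub_seed(seed, 7919 * match(v, vars) + k)),
        numeric(1))
      tab[v, a] <- mean(vals)
    }
  }
  out <- as.data.frame(tab)
  out$Mean <- rowMeans(tab, na.rm = TRUE)
  out
}
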