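#' Build a TSS-gated ensemble
#'
#' Keeps every non-failed model whose validation TSS is at or above the gate
#' (default 0.8) and combines them either by committee averaging (each
#' member binarized at its own TSS-optimal cutoff, cellwise mean of the
#' binaries) or by a weighted mean of the continuous member scores with
#' TSS-proportional weights. Ensemble outputs live on the conventional
#' integer 0-1000 habitat-suitability scale (half-up rounding).
#'
#' @param suite an `sdm_suite` (or plain list of `sdm_model`).
#' @param gate minimum validation TSS for membership (default 0.8).
#' @param method "committee" or "weighted".
#' @return object of class `sdm_ensemble`.
#' @export
build_ensemble <- function(suite, gate = 0.8, method = c("committee", "weighted")) {
  method <- match.arg(method)
  models <- if (inherits(suite, "sdm_suite")) suite$models else suite
  ok <- Filter(function(m) !m$failed && !is.null(m$eval), models)
  if (length(ok) == 0L) stopf("no evaluable models in suite")
  tss <- unname(vapply(ok, function(m) m$eval$tss, numeric(1)))
  pass <- tss >= gate
  if (!any(pass))
    stopf("no model passes the TSS >= %g gate (best TSS = %.3f)", gate, max(tss))
  members <- ok[pass]
  w <- if (method == "weighted") tss[pass] / sum(tss[pass])
       else rep(1 / sum(pass), sum(pass))
  structure(list(method = method, gate = gate, members = members,
                 weights = w,
                 thresholds = vapply(members, function(m) m$eval$tss_threshold,
                                     numeric(1)),
                 member_ids = names(ok)[pass],
                 eval = NULL),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("sdm_ensemble (%s): %d member(s), TSS gate %g\n",
              x$method, length(x$members), x$gate))
  if (!is.null(x$eval))
    cat(sprintf("  pooled evaluation: AUC %.3f TSS %.3f at cutoff %.3f\n",
                x$eval$auc, x$eval$tss, x$eval$tss_threshold))
  invisible(x)
}

# Continuous [0,1] ensemble score for rows of a predictor data.frame.
ensemble_score <- function(ensemble, newdata) {
  preds <- vapply(ensemble$members, function(m) predict(m, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  if (ensemble$method == "committee") {
    bin <- sweep(preds, 2L, ensemble$thresholds, `>=`) * 1
    rowMeans(bin)
  } else {
    as.numeric(preds %*% ensemble$weights)
  }
}

#' Predict ensemble suitability (0-1000) for a predictor table
#' @param object an `sdm_ensemble`.
#' @param newdata data.frame of predictor values.
#' @param ... unused.
#' @return integer vector on the 0-1000 suitability scale.
#' @export
predict.sdm_ensemble <- function(object, newdata, ...) {
  as.integer(round_half_up(1000 * ensemble_score(object, newdata)))
}

#' Project an ensemble onto a raster stack
#'
#' Applies every member to each valid cell and combines per the ensemble
#' method; nodata propagates.
#'
#' @param ensemble an `sdm_ensemble`.
#' @param stack `raster_stack` providing every model predictor.
#' @param scenario label stored on the output layer name.
#' @return single-layer `raster_stack` with integer values 0-1000.
#' @export
project_ensemble <- function(ensemble, stack, scenario = "current") {
  need <- ensemble$members[[1L]]$predictors
  missing <- setdiff(need, layer_names(stack))
  if (length(missing))
    stopf("stack lacks predictor(s): %s", paste(missing, collapse = ", "))
  d <- stack_dim(stack)
  ok <- which(stack_mask(stack))
  out <- matrix(NA_real_, d[1], d[2])
  if (length(ok)) {
    X <- as.data.frame(lapply(stack$layers[need], function(m) m[ok]),
                       optional = TRUE)
    out[ok] <- round_half_up(1000 * ensemble_score(ensemble, X))
  }
  lst <- list(out)
  names(lst) <- paste0("suitability_", scenario)
  raster_stack(lst, xll = stack$xll, yll = stack$yll,
               cellsize = stack$cellsize, crs = stack$crs)
}

#' Evaluate an ensemble by pooling members' validation folds
#'
#' Each data row is scored by the members for which that row was held out
#' (binarized members for the committee method, weight-renormalized
#' continuous scores for the weighted method); AUC and threshold-optimized
#' TSS are then computed over all pooled rows.
#'
#' @param ensemble an `sdm_ensemble`.
#' @param dataset the [modeling_dataset()] the suite was fitted on.
#' @return the ensemble with its `eval` field set (an `evaluation_result`).
#' @export
evaluate_ensemble <- function(ensemble, dataset) {
  n <- length(dataset$y)
  num <- numeric(n); den <- numeric(n)
  for (k in seq_along(ensemble$members)) {
    m <- ensemble$members[[k]]
    v <- m$val_idx
    if (length(v) == 0L) next
    p <- predict(m, dataset$X[v, , drop = FALSE])
    contrib <- if (ensemble$method == "committee")
      as.numeric(p >= ensemble$thresholds[k]) else p
    wk <- if (ensemble$method == "committee") 1 else ensemble$weights[k]
    num[v] <- num[v] + wk * contrib
    den[v] <- den[v] + wk
  }
  use <- den > 0
  if (!any(use)) stopf("no pooled validation rows available")
  scores <- num[use] / den[use]
  ensemble$eval <- tss_optimize(dataset$y[use], scores)
  ensemble
}
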