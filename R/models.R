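#' @name sdm_algorithms
#' @title The nine-algorithm suite
#' @description
#' The fixed algorithm set, in canonical order: GLM (logistic regression),
#' GBM (gradient-boosted trees), GAM (spline additive model), CTA (single
#' classification tree), ANN (one-hidden-layer neural network), SRE (surface
#' range envelope on presence quantiles), FDA (discriminant analysis on a
#' linear+quadratic basis), RF (random forest), and MAXENT (an
#' L1-regularized logistic model on linear+quadratic features, a
#' Java-free stand-in with the same scorer contract). Every fitted model
#' exposes one contract: `predict()` maps a predictor data.frame to scores
#' in [0, 1]; SRE emits only {0, 1}.
NULL

#' @rdname sdm_algorithms
#' @export
SDM_ALGORITHMS <- c("GLM", "GBM", "GAM", "CTA", "ANN", "SRE", "FDA", "RF", "MAXENT")

# Fixed conservative hyperparameters (none are tuned per dataset).
sdm_defaults <- function() {
  list(gbm_nrounds = 150, gbm_eta = 0.1, gbm_depth = 3,
       gam_k = 4, cta_cp = 0.01, ann_size = 5, ann_decay = 0.01,
       ann_maxit = 500, rf_ntree = 500, sre_quantile = 0.025,
       maxent_nfolds = 5)
}

quad_expand <- function(X) {
  Q <- cbind(as.matrix(X), as.matrix(X)^2)
  colnames(Q) <- c(colnames(X), paste0(colnames(X), "_sq"))
  Q
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl,
       apply = function(M) sweep(sweep(as.matrix(M), 2L, ctr), 2L, scl, "/"))
}

# ---- per-algorithm fit/predict -------------------------------------------

fit_algorithm <- function(algorithm, X, y, w, seed, params) {
  p <- utils::modifyList(sdm_defaults(), params)
  switch(algorithm,
    GLM = {
      # quadratic polynomial response, the standard GLM-SDM specification
      # (a linear logistic cannot represent a unimodal niche)
      d <- cbind(X, .y = y)
      rhs <- paste(vapply(names(X), function(v)
        sprintf("%s + I(%s^2)", v, v), ""), collapse = " + ")
      list(fit = suppressWarnings(
        stats::glm(stats::as.formula(paste(".y ~", rhs)), data = d,
                   family = stats::binomial(), weights = w)))
    },
    GAM = {
      terms <- vapply(names(X), function(v) {
        k <- min(p$gam_k, length(unique(X[[v]])) - 1L)
        if (k >= 3) sprintf("s(%s, k = %d)", v, k) else v
      }, "")
      d <- cbind(X, .y = y)
      list(fit = suppressWarnings(mgcv::gam(
        stats::as.formula(paste(".y ~", paste(terms, collapse = " + "))),
        data = d, family = stats::binomial(), weights = w, method = "REML")))
    },
    GBM = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, weight = w)
      list(fit = xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = p$gbm_eta,
                      max_depth = p$gbm_depth, nthread = 1),
        data = dtrain, nrounds = p$gbm_nrounds, verbose = 0))
    },
    CTA = {
      d <- cbind(X, .y = factor(y, levels = c(0, 1)))
      list(fit = rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                              control = rpart::rpart.control(cp = p$cta_cp)))
    },
    ANN = {
      std <- standardizer(X)
      fit <- with_seed(seed, nnet::nnet(
        x = std$apply(X), y = y, weights = w, size = p$ann_size,
        decay = p$ann_decay, maxit = p$ann_maxit, entropy = TRUE,
        trace = FALSE))
      list(fit = fit, std = std)
    },
    SRE = {
      q <- p$sre_quantile
      pres <- X[y == 1L, , drop = FALSE]
      list(lo = apply(pres, 2L, stats::quantile, probs = q, names = FALSE),
           hi = apply(pres, 2L, stats::quantile, probs = 1 - q, names = FALSE))
    },
    FDA = {
      std <- standardizer(quad_expand(X))
      fit <- MASS::lda(std$apply(quad_expand(X)),
                       grouping = factor(y, levels = c(0, 1)),
                       prior = c(0.5, 0.5))
      list(fit = fit, std = std)
    },
    RF = {
      fit <- with_seed(seed, randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)), ntree = p$rf_ntree))
      list(fit = fit)
    },
    MAXENT = {
      Q <- quad_expand(X)
      std <- standardizer(Q)
      fit <- with_seed(seed, glmnet::cv.glmnet(
        std$apply(Q), y, family = "binomial", alpha = 1, weights = w,
        nfolds = p$maxent_nfolds))
      list(fit = fit, std = std)
    },
    stopf("unknown algorithm '%s' (expected one of %s)", algorithm,
          paste(SDM_ALGORITHMS, collapse = ", ")))
}

predict_algorithm <- function(algorithm, obj, X) {
  out <- switch(algorithm,
    GLM = stats::predict(obj$fit, newdata = X, type = "response"),
    GAM = as.numeric(stats::predict(obj$fit, newdata = X, type = "response")),
    GBM = stats::predict(obj$fit, xgboost::xgb.DMatrix(as.matrix(X))),
    CTA = stats::predict(obj$fit, newdata = X, type = "prob")[, "1"],
    ANN = as.numeric(stats::predict(obj$fit, obj$std$apply(X))),
    SRE = {
      M <- as.matrix(X)
      inside <- rep(TRUE, nrow(M))
      for (j in seq_len(ncol(M)))
        inside <- inside & M[, j] >= obj$lo[j] & M[, j] <= obj$hi[j]
      as.numeric(inside)
    },
    FDA = stats::predict(obj$fit, obj$std$apply(quad_expand(X)))$posterior[, "1"],
    RF = stats::predict(obj$fit, newdata = X, type = "prob")[, "1"],
    MAXENT = as.numeric(stats::predict(obj$fit, obj$std$apply(quad_expand(X)),
                                       s = "lambda.min", type = "response")))
  pmin(pmax(as.numeric(out), 0), 1)
}

#' Fit one algorithm on one repetition
#'
#' Trains on the repetition's training fold only and evaluates (ROC-AUC and
#' threshold-optimized TSS) on the held-out validation fold. A degenerate
#' training fold (a single class) yields a failed-model record rather than
#' an error, so suites degrade gracefully.
#'
#' @param algorithm one of [SDM_ALGORITHMS].
#' @param dataset a [modeling_dataset()].
#' @param repetition repetition index (column of `splits`).
#' @param splits logical train/validation matrix from [make_splits()].
#' @param seed RNG seed for the stochastic learners (ANN, RF, MAXENT folds).
#' @param params named list overriding entries of the fixed hyperparameter
#'   defaults.
#' @return object of class `sdm_model` (fields: `algorithm`, `repetition`,
#'   `eval`, `failed`, ...); `predict()` returns scores in [0, 1].
#' @export
fit <- function(algorithm, dataset, repetition, splits, seed = 1,
                params = list()) {
  algorithm <- match.arg(algorithm, SDM_ALGORITHMS)
  if (repetition < 1L || repetition > ncol(splits))
    stopf("repetition %d outside 1..%d", repetition, ncol(splits))
  tr <- splits[, repetition]
  base <- structure(list(algorithm = algorithm, repetition = repetition,
                         predictors = dataset$predictors, failed = TRUE,
                         reason = NULL, eval = NULL, train_idx = which(tr),
                         val_idx = which(!tr)),
                    class = "sdm_model")
  ytr <- dataset$y[tr]
  if (length(unique(ytr)) < 2L) {
    base$reason <- "degenerate training fold: a single class"
    return(base)
  }
  obj <- tryCatch(
    fit_algorithm(algorithm, dataset$X[tr, , drop = FALSE], ytr,
                  dataset$weights[tr], seed, params),
    error = function(e) e)
  if (inherits(obj, "error")) {
    base$reason <- conditionMessage(obj)
    return(base)
  }
  base$failed <- FALSE
  base$object <- obj
  val <- !tr
  if (any(val) && length(unique(dataset$y[val])) == 2L) {
    preds <- predict_algorithm(algorithm, obj, dataset$X[val, , drop = FALSE])
    base$eval <- tss_optimize(dataset$y[val], preds)
  }
  base
}

#' @export
predict.sdm_model <- function(object, newdata, ...) {
  if (object$failed) stopf("cannot predict from failed model (%s)", object$reason)
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing))
    stopf("missing predictor(s): %s", paste(missing, collapse = ", "))
  predict_algorithm(object$algorithm, object$object,
                    as.data.frame(newdata)[, object$predictors, drop = FALSE])
}

#' @export
print.sdm_model <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("sdm_model %s rep %d: FAILED (%s)\n", x$algorithm,
                x$repetition, x$reason))
  } else {
    cat(sprintf("sdm_model %s rep %d: AUC %.3f TSS %.3f\n", x$algorithm,
                x$repetition, x$eval$auc, x$eval$tss))
  }
  invisible(x)
}

#' Fit the full algorithm suite across repetitions
#'
#' Nine algorithms times `reps` stratified 80/20 repetitions (27 models at
#' the defaults), each evaluated on its own held-out fold. Per-model
#' failures are recorded and propagated, never fatal.
#'
#' @param dataset a [modeling_dataset()].
#' @param reps number of split repetitions (default 3).
#' @param train_frac training fraction (default 0.8).
#' @param seed RNG seed; splits and every stochastic learner derive
#'   sub-seeds from it.
#' @param algorithms algorithm subset (default all nine).
#' @param params hyperparameter overrides passed to every [fit()].
#' @return object of class `sdm_suite`: list of `sdm_model` plus the splits.
#' @export
fit_suite <- function(dataset, reps = 3, train_frac = 0.8, seed = 1,
                      algorithms = SDM_ALGORITHMS, params = list()) {
  splits <- make_splits(dataset, train_frac = train_frac, reps = reps,
                        seed = sub_seed(seed, 1000))
  models <- list()
  for (r in seq_len(reps)) {
    for (a in algorithms) {
      m <- fit(a, dataset, r, splits,
               seed = sub_seed(seed, 100 * r + match(a, SDM_ALGORITHMS)),
               params = params)
      models[[paste0(a, "_rep", r)]] <- m
    }
  }
  structure(list(models = models, splits = splits, dataset_n = length(dataset$y),
                 algorithms = algorithms, reps = reps, seed = seed),
            class = "sdm_suite")
}

#' @export
print.sdm_suite <- function(x, ...) {
  ok <- !vapply(x$models, `[[`, logical(1), "failed")
  cat(sprintf("sdm_suite: %d models (%d ok, %d failed), %d algorithms x %d reps\n",
              length(x$models), sum(ok), sum(!ok), length(x$algorithms), x$reps))
  invisible(x)
}

#' Per-model evaluation scores of a suite
#' @param suite an `sdm_suite`.
#' @return data.frame: algorithm, repetition, failed, auc, tss, tss_threshold.
#' @export
suite_scores <- function(suite) {
  do.call(rbind, lapply(suite$models, function(m) {
    data.frame(algorithm = m$algorithm, repetition = m$repetition,
               failed = m$failed,
               auc = if (!is.null(m$eval)) m$eval$auc else NA_real_,
               tss = if (!is.null(m$eval)) m$eval$tss else NA_real_,
               tss_threshold = if (!is.null(m$eval)) m$eval$tss_threshold else NA_real_)
  })) -> df
  rownames(df) <- NULL
  df
}
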