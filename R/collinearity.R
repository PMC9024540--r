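#' Pairwise Pearson correlation among predictor layers
#'
#' Computes the standard Pearson correlation for every layer pair, by default
#' over all valid (non-nodata) cells of the stack; pass occurrence points to
#' restrict the sample to their cells instead. Zero-variance layers have no
#' defined correlation: they are dropped from the matrix with a warning.
#'
#' @param stack a `raster_stack`.
#' @param points optional [occurrence_set()]; when given, correlations are
#'   computed over the values at those points only.
#' @return symmetric correlation matrix (unit diagonal) over the retained
#'   layers.
#' @export
correlation_matrix <- function(stack, points = NULL) {
  if (is.null(points)) {
    ok <- which(stack_mask(stack))
    X <- vapply(stack$layers, function(m) m[ok], numeric(length(ok)))
  } else {
    X <- as.matrix(extract_values(stack, points$lon, points$lat))
    X <- X[stats::complete.cases(X), , drop = FALSE]
  }
  if (nrow(X) < 3L) stopf("need >= 3 valid samples to compute correlations")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping zero-variance layer(s): %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0L) stopf("no layer with non-zero variance")
  stats::cor(X)
}

#' Greedy collinearity filter on a correlation matrix
#'
#' Iterates over layers in `priority` order (default: the matrix's own
#' order) and keeps a layer iff its absolute correlation with every
#' already-kept layer is at or below `threshold`. The retained set therefore
#' carries a certificate: max pairwise |r| <= threshold. The representative
#' of a correlated group is whichever member comes first in the priority
#' order — this ordering is the reproducibility knob, since the filter's
#' outcome is not unique without it.
#'
#' @param matrix square symmetric correlation matrix with named dimensions.
#' @param threshold maximum tolerated absolute pairwise correlation
#'   (default 0.75, the conventional collinearity cutoff for bioclimatic
#'   variables).
#' @param priority character vector of layer names; layers listed here are
#'   considered first (in the given order), remaining layers follow in
#'   matrix order.
#' @return object of class `correlation_report`: list with `matrix`,
#'   `threshold`, `retained` (ordered names), and `dropped` (named character
#'   vector mapping each dropped layer to the retained layer that excluded
#'   it).
#' @export
select_uncorrelated <- function(matrix, threshold = 0.75, priority = NULL) {
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
    stopf("correlation matrix must be square and symmetric")
  nms <- rownames(m) %||% colnames(m) %||% paste0("layer_", seq_len(nrow(m)))
  rownames(m) <- colnames(m) <- nms
  order_nms <- c(intersect(priority %||% character(0), nms),
                 setdiff(nms, priority %||% character(0)))
  retained <- character(0)
  dropped <- character(0)
  for (nm in order_nms) {
    if (length(retained) == 0L) { retained <- nm; next }
    r <- abs(m[nm, retained])
    if (all(r <= threshold | is.na(r))) {
      retained <- c(retained, nm)
    } else {
      blocker <- retained[which.max(ifelse(is.na(r), -Inf, r))]
      dropped[nm] <- blocker
    }
  }
  sub <- abs(m[retained, retained, drop = FALSE])
  diag(sub) <- 0
  if (any(sub > threshold, na.rm = TRUE))
    stopf("internal error: retained set violates the |r| <= %g certificate",
          threshold)
  structure(list(matrix = m, threshold = threshold, retained = retained,
                 dropped = dropped,
                 max_retained_r = if (length(retained) > 1L)
                   max(sub, na.rm = TRUE) else 0),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d/%d layers retained at |r| <= %g (max retained |r| = %g)\n",
              length(x$retained), nrow(x$matrix), x$threshold, x$max_retained_r))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped :", paste(sprintf("%s (vs %s)", names(x$dropped), x$dropped),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Export a correlation report (matrix CSV + retained-list JSON)
#' @param report a `correlation_report`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_correlation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, "correlation_matrix.csv")
  utils::write.csv(report$matrix, mpath)
  jpath <- file.path(dir, "retained_layers.json")
  jsonlite::write_json(list(threshold = report$threshold,
                            retained = as.list(report$retained),
                            dropped = as.list(report$dropped),
                            max_retained_r = report$max_retained_r),
                       jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(mpath, jpath))
}
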