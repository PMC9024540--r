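#' Sample pseudo-absence points
#'
#' Draws `n` cells uniformly at random, without replacement, from the valid
#' cells of the stack that do not contain a presence. Coordinates are cell
#' centers.
#'
#' @param stack a `raster_stack`.
#' @param occ an [occurrence_set()] of presences.
#' @param n number of pseudo-absences (default 10000, the conventional
#'   background size for regression-type SDM algorithms).
#' @param seed RNG seed.
#' @return data.frame with `lon`, `lat`, `cell`.
#' @export
sample_pseudo_absences <- function(stack, occ, n = 10000, seed = 1) {
  if (n < 1) stopf("n must be >= 1")
  valid <- which(stack_mask(stack))
  pres_cells <- unique(cell_from_lonlat(stack, occ$lon, occ$lat)$cell)
  eligible <- setdiff(valid, pres_cells)
  if (n > length(eligible))
    stopf("requested %d pseudo-absences but only %d eligible cells (%d valid, %d presence)",
          n, length(eligible), length(valid), length(stats::na.omit(pres_cells)))
  cells <- with_seed(seed,
    if (length(eligible) == 1L) eligible else sample(eligible, n))
  cc <- cell_centers(stack)
  data.frame(lon = cc$lon[cells], lat = cc$lat[cells], cell = cells)
}

#' Assemble a presence / pseudo-absence modeling dataset
#'
#' Extracts the retained predictor values at presence and pseudo-absence
#' cells, deduplicates presences to one per cell, drops rows with missing
#' predictors (with a warning), and down-weights pseudo-absences so the
#' total absence weight equals the total presence weight (the "prevalence
#' 0.5" convention, so algorithms see a balanced problem regardless of the
#' background size).
#'
#' @param stack `raster_stack` restricted to the retained predictors (use
#'   [subset_stack()] after [select_uncorrelated()]).
#' @param occ presence [occurrence_set()].
#' @param pa pseudo-absence points from [sample_pseudo_absences()].
#' @return object of class `modeling_dataset`: list with `X` (data.frame),
#'   `y` (0/1), `weights`, `cell` (grid cell per row), `predictors`.
#' @export
modeling_dataset <- function(stack, occ, pa) {
  pres_cell <- cell_from_lonlat(stack, occ$lon, occ$lat)$cell
  dup <- duplicated(pres_cell) | is.na(pres_cell)
  pres_cell <- pres_cell[!dup]
  overlap <- intersect(pres_cell, pa$cell)
  if (length(overlap))
    stopf("%d pseudo-absence cell(s) coincide with presence cells", length(overlap))
  cells <- c(pres_cell, pa$cell)
  y <- c(rep(1L, length(pres_cell)), rep(0L, nrow(pa)))
  X <- as.data.frame(lapply(stack$layers, function(m) m[cells]),
                     optional = TRUE)
  ok <- stats::complete.cases(X)
  if (!all(ok)) {
    warnf("dropping %d row(s) with missing predictor values", sum(!ok))
    X <- X[ok, , drop = FALSE]; y <- y[ok]; cells <- cells[ok]
  }
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stopf("dataset needs both presences and pseudo-absences")
  w <- ifelse(y == 1L, 1, sum(y == 1L) / sum(y == 0L))
  structure(list(X = X, y = y, weights = w, cell = cells,
                 predictors = layer_names(stack)),
            class = "modeling_dataset")
}

#' Repeated stratified train/validation splits
#'
#' Per repetition, a stratified random split: `train_frac` of the presences
#' and `train_frac` of the absences (rounded) go to training, preserving
#' class proportions within one point.
#'
#' @param dataset a [modeling_dataset()].
#' @param train_frac training fraction (default 0.8).
#' @param reps number of repetitions (default 3).
#' @param seed RNG seed (each repetition uses a derived sub-seed).
#' @return logical matrix `n x reps`; TRUE = training row.
#' @export
make_splits <- function(dataset, train_frac = 0.8, reps = 3, seed = 1) {
  y <- dataset$y
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stopf("each class needs >= 2 points to split")
  if (train_frac <= 0 || train_frac >= 1) stopf("train_frac must be in (0,1)")
  n <- length(y)
  out <- matrix(FALSE, n, reps)
  for (r in seq_len(reps)) {
    out[, r] <- with_seed(sub_seed(seed, r), {
      tr <- logical(n)
      for (cls in c(0L, 1L)) {
        idx <- which(y == cls)
        k <- round(train_frac * length(idx))
        k <- min(max(k, 1L), length(idx) - 1L)   # both folds keep the class
        tr[sample(idx, k)] <- TRUE
      }
      tr
    })
  }
  out
}
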