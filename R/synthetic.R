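#' Specification for a synthetic climate layer set
#'
#' Describes a set of climate-like predictor layers: spatially autocorrelated
#' Gaussian fields with a prescribed cross-layer Pearson correlation
#' structure, on a regular lon/lat grid. Stands in for real bioclimatic
#' layer sets (bio_1..bio_19-style) so the whole pipeline runs against known
#' ground truth.
#'
#' @param n_layers number of layers (>= 1).
#' @param grid_shape integer c(rows, cols), both >= 10.
#' @param spatial_range correlation length in cells (> 0); width of the
#'   moving-average smoothing kernel.
#' @param cross_correlation target layer-pair correlation matrix (symmetric,
#'   unit diagonal, positive semi-definite). Default: identity.
#' @param nodata_fraction fraction of cells masked as nodata, in [0, 1).
#' @param layer_means,layer_sds marginal mean and sd per layer (recycled);
#'   defaults 0 and 1 (standardized anomaly fields).
#' @param seed integer RNG seed.
#' @return an object of class `climate_spec`.
#' @export
climate_spec <- function(n_layers, grid_shape, spatial_range = 5,
                         cross_correlation = NULL, nodata_fraction = 0,
                         layer_means = 0, layer_sds = 1, seed = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 10L))
    stopf("grid_shape must be c(rows, cols) with both dims >= 10")
  if (n_layers < 1L) stopf("n_layers must be >= 1")
  if (spatial_range <= 0) stopf("spatial_range must be > 0")
  if (nodata_fraction < 0 || nodata_fraction >= 1)
    stopf("nodata_fraction must be in [0, 1)")
  C <- cross_correlation %||% diag(n_layers)
  C <- as.matrix(C)
  if (!isTRUE(all.equal(dim(C), c(n_layers, n_layers), check.attributes = FALSE)))
    stopf("cross_correlation must be %d x %d", n_layers, n_layers)
  if (max(abs(C - t(C))) > 1e-8 || max(abs(diag(C) - 1)) > 1e-8)
    stopf("cross_correlation must be symmetric with unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stopf("cross_correlation is not positive semi-definite (min eigenvalue %.3g)",
          min(ev))
  structure(list(n_layers = as.integer(n_layers), grid_shape = grid_shape,
                 spatial_range = spatial_range, cross_correlation = C,
                 nodata_fraction = nodata_fraction,
                 layer_means = rep_len(layer_means, n_layers),
                 layer_sds = rep_len(layer_sds, n_layers),
                 seed = as.integer(seed)),
            class = "climate_spec")
}

# Separable box-filter smoothing with edge renormalization.
smooth_field <- function(m, width) {
  w <- max(1L, as.integer(round(width)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(m)
  k <- rep(1, w)
  pad <- (w - 1L) / 2L
  run <- function(x) {
    n <- length(x)
    s <- stats::filter(c(rep(0, pad), x, rep(0, pad)), k, sides = 2)
    cnt <- stats::filter(c(rep(0, pad), rep(1, n), rep(0, pad)), k, sides = 2)
    (s / cnt)[(pad + 1L):(pad + n)]
  }
  m <- apply(m, 2L, run)
  t(apply(m, 1L, run))
}

#' Generate a synthetic climate layer stack
#'
#' Draws independent white-noise fields, smooths each with a moving-average
#' kernel of width `spatial_range` (spatial autocorrelation), orthonormalizes
#' the smoothed fields and mixes them through the matrix square root of the
#' target correlation matrix, so the empirical cross-layer Pearson
#' correlations match the target (exactly on a fully valid grid, closely once
#' a nodata mask is applied). Output is a pure function of the spec (its
#' embedded seed): identical spec, identical arrays.
#'
#' @param spec a [climate_spec()].
#' @return a `raster_stack` with layers `env_1`, `env_2`, ...
#' @export
generate_climate <- function(spec) {
  stopifnot(inherits(spec, "climate_spec"))
  d <- spec$grid_shape
  ncell <- prod(d)
  with_seed(spec$seed, {
    F <- vapply(seq_len(spec$n_layers), function(i)
      as.vector(smooth_field(matrix(stats::rnorm(ncell), d[1], d[2]),
                             spec$spatial_range)),
      numeric(ncell))
    F <- scale(F, center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(F))                       # orthonormal smooth fields
    C <- spec$cross_correlation
    ev <- eigen(C, symmetric = TRUE)
    S <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow = nrow(C)) %*%
      t(ev$vectors)                        # symmetric PSD square root
    X <- Q %*% S * sqrt(ncell - 1)         # unit-sd columns, cor(X) = C
    mask_idx <- integer(0)
    if (spec$nodata_fraction > 0)
      mask_idx <- sample.int(ncell, floor(spec$nodata_fraction * ncell))
    layers <- lapply(seq_len(spec$n_layers), function(i) {
      v <- spec$layer_means[i] + spec$layer_sds[i] * X[, i]
      v[mask_idx] <- NA_real_
      matrix(v, d[1], d[2])
    })
    names(layers) <- paste0("env_", seq_len(spec$n_layers))
    # 0.05 degree cells (~5 km): climate-raster-like, and any grid up to
    # 1800 rows stays inside valid lat/lon bounds
    raster_stack(layers, xll = 0, yll = 0, cellsize = 0.05)
  })
}

#' Define a virtual species
#'
#' The species responds to a subset of layers (`driving_layers`) through
#' independent Gaussian response curves; true habitat suitability is the
#' product of per-layer responses rescaled to max 1. Non-driving layers have
#' no effect, which gives downstream variable-importance checks a ground
#' truth.
#'
#' @param driving_layers layer names (or indices) the species responds to.
#' @param response_means optimum value per driving layer.
#' @param response_widths Gaussian response width (sd) per driving layer, > 0.
#' @param prevalence_target intended fraction of the landscape that is
#'   suitable, in (0, 1); recorded for calibration checks.
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(driving_layers, response_means, response_widths,
                            prevalence_target = 0.1) {
  if (length(driving_layers) == 0L) stopf("driving_layers must be non-empty")
  if (any(response_widths <= 0)) stopf("response_widths must be > 0")
  if (length(response_means) != length(driving_layers) ||
      length(response_widths) != length(driving_layers))
    stopf("response_means/response_widths must match driving_layers in length")
  if (prevalence_target <= 0 || prevalence_target >= 1)
    stopf("prevalence_target must be in (0, 1)")
  structure(list(driving_layers = driving_layers,
                 response_means = response_means,
                 response_widths = response_widths,
                 prevalence_target = prevalence_target),
            class = "virtual_species")
}

#' True habitat suitability of a virtual species
#'
#' Product of per-layer Gaussian responses over the driving layers, rescaled
#' so the best valid cell has suitability 1. Nodata propagates.
#'
#' @param stack a `raster_stack` containing every driving layer.
#' @param sp a [virtual_species()].
#' @return a single-layer `raster_stack` (`suitability`, values in [0, 1]).
#' @export
true_suitability <- function(stack, sp) {
  drv <- sp$driving_layers
  if (is.numeric(drv)) drv <- layer_names(stack)[drv]
  missing <- setdiff(drv, layer_names(stack))
  if (length(missing))
    stopf("driving layer(s) absent from stack: %s", paste(missing, collapse = ", "))
  d <- stack_dim(stack)
  suit <- matrix(1, d[1], d[2])
  for (i in seq_along(drv)) {
    z <- (stack$layers[[drv[i]]] - sp$response_means[i]) / sp$response_widths[i]
    suit <- suit * exp(-0.5 * z^2)
  }
  if (all(is.na(suit))) stopf("stack has no valid cells")
  mx <- max(suit, na.rm = TRUE)
  if (mx > 0) suit <- suit / mx
  raster_stack(list(suitability = suit), xll = stack$xll, yll = stack$yll,
               cellsize = stack$cellsize, crs = stack$crs)
}

#' Sample presence records from a suitability surface
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability (at most one presence per cell); coordinates are the cell
#' centers.
#'
#' @param suit single-layer `raster_stack` as returned by [true_suitability()].
#' @param n number of presences (>= 1).
#' @param seed RNG seed.
#' @param species species label for the output.
#' @return an [occurrence_set()] with `source = "synthetic"`.
#' @export
sample_occurrences <- function(suit, n, seed = 1, species = "virtual_sp") {
  if (n < 1) stopf("n must be >= 1")
  s <- suit$layers[[1L]]
  eligible <- which(!is.na(s) & s > 0)
  if (n > length(eligible))
    stopf("n = %d exceeds the %d cells with positive suitability", n,
          length(eligible))
  cells <- with_seed(seed,
    if (length(eligible) == 1L) eligible
    else sample(eligible, n, prob = s[eligible]))
  cc <- cell_centers(suit)
  occurrence_set(data.frame(species = species,
                            lon = cc$lon[cells], lat = cc$lat[cells],
                            source = "synthetic"))
}

#' Define a climate-change scenario as per-layer affine shifts
#'
#' @param additive_deltas per-layer additive offsets (recycled).
#' @param multiplicative_deltas per-layer multiplicative factors (> 0).
#' @return an object of class `scenario_shift`.
#' @export
scenario_shift <- function(additive_deltas = 0, multiplicative_deltas = 1) {
  if (any(multiplicative_deltas <= 0)) stopf("multiplicative factors must be > 0")
  structure(list(additive_deltas = additive_deltas,
                 multiplicative_deltas = multiplicative_deltas),
            class = "scenario_shift")
}

#' Apply a scenario shift to a layer stack
#'
#' `layer' = layer * factor + offset`, per layer; the nodata mask is
#' unchanged, so valid-cell counts are conserved across scenarios.
#'
#' @param stack a `raster_stack`.
#' @param shift a [scenario_shift()]; delta lengths must be 1 or `n_layers`.
#' @return the shifted `raster_stack`.
#' @export
apply_scenario <- function(stack, shift) {
  stopifnot(inherits(shift, "scenario_shift"))
  k <- n_layers(stack)
  add <- shift$additive_deltas
  mul <- shift$multiplicative_deltas
  if (!length(add) %in% c(1L, k) || !length(mul) %in% c(1L, k))
    stopf("delta length (%d add, %d mul) must be 1 or n_layers = %d",
          length(add), length(mul), k)
  add <- rep_len(add, k); mul <- rep_len(mul, k)
  layers <- stack$layers
  for (i in seq_len(k)) layers[[i]] <- layers[[i]] * mul[i] + add[i]
  raster_stack(layers, xll = stack$xll, yll = stack$yll,
               cellsize = stack$cellsize, crs = stack$crs)
}
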