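#' PCA of environmental space calibrated on pooled backgrounds
#'
#' The PCA-env convention: a principal component analysis on the
#' centered+scaled pooled background samples of the two periods being
#' compared, so both periods are projected with one set of loadings and
#' their niches live in the same two-dimensional space. Constant predictors
#' are dropped with a warning.
#'
#' @param env_samples_current,env_samples_future data.frames/matrices of
#'   predictor values sampled from each period's background (same columns).
#' @return object of class `pca_env`: rotation (predictors x 2), center,
#'   scale, `explained_pct` (variance % of PC1 and PC2).
#' @export
fit_pca_env <- function(env_samples_current, env_samples_future) {
  a <- as.data.frame(env_samples_current)
  b <- as.data.frame(env_samples_future)
  if (!identical(sort(names(a)), sort(names(b))))
    stopf("the two periods must share predictor columns")
  pooled <- rbind(a, b[, names(a), drop = FALSE])
  if (nrow(pooled) < 3L || ncol(pooled) < 2L)
    stopf("need >= 3 samples and >= 2 predictors")
  sds <- vapply(pooled, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warnf("dropping constant predictor(s): %s",
          paste(names(pooled)[sds == 0], collapse = ", "))
    pooled <- pooled[, sds > 0, drop = FALSE]
    if (ncol(pooled) < 2L) stopf("fewer than 2 non-constant predictors")
  }
  p <- stats::prcomp(pooled, center = TRUE, scale. = TRUE)
  expl <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(rotation = p$rotation[, 1:2, drop = FALSE],
                 center = p$center, scale = p$scale,
                 explained_pct = expl[1:2], predictors = colnames(pooled)),
            class = "pca_env")
}

#' Project environmental samples into PCA-env space
#' @param model a `pca_env`.
#' @param newdata data.frame with the model's predictor columns.
#' @return matrix n x 2 of PC scores.
#' @export
project_pca <- function(model, newdata) {
  X <- as.matrix(as.data.frame(newdata)[, model$predictors, drop = FALSE])
  scale(X, center = model$center, scale = model$scale) %*% model$rotation
}

bw_nrd_safe <- function(x, lim) {
  h <- tryCatch(MASS::bandwidth.nrd(x), error = function(e) 0)
  if (!is.finite(h) || h <= 0) h <- diff(lim) / 25
  h
}

#' Kernel-density occupancy grid in PCA-env space
#'
#' Gaussian kernel densities of the occurrences and of the background on an
#' R x R grid spanning the background envelope (normal-reference bandwidth
#' per axis); the occupancy surface is `z = occ_density / env_density`
#' wherever the background density is positive, normalized to sum 1. The
#' division corrects the raw occurrence density for how much of each
#' environment is available at all.
#'
#' @param pca_scores_background n x 2 background scores (defines the grid
#'   extent unless `extent` is given).
#' @param pca_scores_occurrences m x 2 occurrence scores (m >= 5).
#' @param R grid resolution per axis (default 100).
#' @param extent optional list(xlim =, ylim =) to share a grid across niches.
#' @return object of class `niche_grid`: `occ_density`, `env_density`, `z`
#'   (all R x R, each summing to 1), `xlim`, `ylim`, `R`.
#' @name density_grid
NULL

env_density_grid <- function(bg, R, extent = NULL) {
  bg <- as.matrix(bg)
  xlim <- extent$xlim %||% range(bg[, 1])
  ylim <- extent$ylim %||% range(bg[, 2])
  kd <- MASS::kde2d(bg[, 1], bg[, 2], n = R, lims = c(xlim, ylim),
                    h = c(bw_nrd_safe(bg[, 1], xlim),
                          bw_nrd_safe(bg[, 2], ylim)))
  list(env = kd$z / sum(kd$z), xlim = xlim, ylim = ylim, R = R)
}

occ_to_grid <- function(envgrid, occ) {
  occ <- as.matrix(occ)
  if (nrow(occ) < 5L) stopf("need >= 5 occurrences (got %d)", nrow(occ))
  xlim <- envgrid$xlim; ylim <- envgrid$ylim
  inside <- occ[, 1] >= xlim[1] & occ[, 1] <= xlim[2] &
            occ[, 2] >= ylim[1] & occ[, 2] <= ylim[2]
  if (!any(inside)) stopf("all occurrences fall outside the background envelope")
  kd_occ <- MASS::kde2d(occ[, 1], occ[, 2], n = envgrid$R,
                        lims = c(xlim, ylim),
                        h = c(bw_nrd_safe(occ[, 1], xlim),
                              bw_nrd_safe(occ[, 2], ylim)))
  od <- kd_occ$z / sum(kd_occ$z)
  env <- envgrid$env
  z <- matrix(0, envgrid$R, envgrid$R)
  pos <- env > 0
  z[pos] <- od[pos] / env[pos]
  if (sum(z) == 0) stopf("occupancy surface is identically zero")
  z <- z / sum(z)
  structure(list(occ_density = od, env_density = env, z = z,
                 xlim = xlim, ylim = ylim, R = envgrid$R),
            class = "niche_grid")
}

#' @rdname density_grid
#' @export
density_grid <- function(pca_scores_background, pca_scores_occurrences,
                         R = 100, extent = NULL) {
  occ_to_grid(env_density_grid(pca_scores_background, R, extent),
              pca_scores_occurrences)
}

as_density <- function(x, warn = TRUE) {
  z <- if (inherits(x, "niche_grid")) x$z else as.matrix(x)
  s <- sum(z)
  if (s <= 0) stopf("density grid has no mass")
  if (abs(s - 1) > 1e-8) {
    if (warn) warnf("input density not normalized (sum = %g); normalizing", s)
    z <- z / s
  }
  z
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)` on two normalized density grids; 0 = no
#' overlap, 1 = identical niches. Symmetric and invariant to cell ordering.
#'
#' @param z1,z2 `niche_grid`s or matrices on the same grid (normalized;
#'   unnormalized input is normalized with a warning).
#' @return D in [0, 1].
#' @export
schoener_d <- function(z1, z2) {
  a <- as_density(z1); b <- as_density(z2)
  if (!identical(dim(a), dim(b))) stopf("density grids differ in shape")
  min(1, max(0, 1 - 0.5 * sum(abs(a - b))))
}

overlap_test_result <- function(D, null, p, reps, alternative) {
  structure(list(D = D, null_distribution = null, p_value = p, reps = reps,
                 alternative = alternative),
            class = "overlap_test_result")
}

#' @export
print.overlap_test_result <- function(x, ...) {
  cat(sprintf("niche overlap D = %.4f | p = %.5f (%s, %d permutations)\n",
              x$D, x$p_value, x$alternative, x$reps))
  invisible(x)
}

#' Niche equivalency permutation test
#'
#' Null: the two occurrence sets are interchangeable draws from one niche.
#' Pools the occurrences, randomly reassigns them to two groups of the
#' original sizes, rebuilds both occupancy grids and recomputes D, `reps`
#' times. With alternative "lower" (the default),
#' `p = (#\{D_null <= D_obs\} + 1) / (reps + 1)`: small p means the observed
#' overlap is lower than expected under interchangeability, rejecting niche
#' equivalency.
#'
#' @param occ1,occ2 n x 2 PCA-score matrices of the two occurrence sets
#'   (>= 5 points each).
#' @param background n x 2 PCA scores of the shared background.
#' @param reps number of permutations (>= 19; default 99).
#' @param seed RNG seed.
#' @param alternative "lower" or "greater".
#' @param R density-grid resolution.
#' @return an `overlap_test_result` (fields `D`, `null_distribution`,
#'   `p_value`, `reps`, `alternative`).
#' @export
equivalency_test <- function(occ1, occ2, background, reps = 99, seed = 1,
                             alternative = c("lower", "greater"), R = 100) {
  alternative <- match.arg(alternative)
  if (reps < 19) stopf("reps must be >= 19")
  occ1 <- as.matrix(occ1); occ2 <- as.matrix(occ2)
  if (nrow(occ1) < 5L || nrow(occ2) < 5L)
    stopf("each occurrence group needs >= 5 points")
  bg <- as.matrix(background)
  envgrid <- env_density_grid(bg, R)
  g1 <- occ_to_grid(envgrid, occ1)
  g2 <- occ_to_grid(envgrid, occ2)
  D_obs <- schoener_d(g1, g2)
  pooled <- rbind(occ1, occ2)
  n1 <- nrow(occ1)
  null <- vapply(seq_len(reps), function(r) with_seed(sub_seed(seed, r), {
    idx <- sample.int(nrow(pooled))
    a <- pooled[idx[seq_len(n1)], , drop = FALSE]
    b <- pooled[idx[-seq_len(n1)], , drop = FALSE]
    schoener_d(occ_to_grid(envgrid, a), occ_to_grid(envgrid, b))
  }), numeric(1))
  p <- if (alternative == "lower") (sum(null <= D_obs) + 1) / (reps + 1)
       else (sum(null >= D_obs) + 1) / (reps + 1)
  overlap_test_result(D_obs, null, p, reps, alternative)
}

# Torus shift of a matrix by (di, dj) cells.
shift_wrap <- function(M, di, dj) {
  n <- nrow(M); m <- ncol(M)
  M[((seq_len(n) - 1 - di) %% n) + 1, ((seq_len(m) - 1 - dj) %% m) + 1]
}

#' Niche similarity permutation test
#'
#' Null: niche 2 sits at a random location within its own background.
#' Each rep translates niche 2's observed occurrence-density surface so its
#' centroid lands on a uniformly chosen background cell (density mass wraps
#' at the grid edges), rebuilds the occupancy surface against the unchanged
#' background density, and recomputes D against niche 1. With alternative
#' "greater" (default), `p = (#\{D_null >= D_obs\} + 1) / (reps + 1)`:
#' small p means the two niches are more similar than chance placement.
#'
#' @param z1 `niche_grid` of the reference niche (defines the shared grid).
#' @param occ2 n x 2 PCA scores of the second niche's occurrences.
#' @param background2 n x 2 PCA scores of the second niche's background.
#' @param reps permutations (>= 19; default 99).
#' @param seed RNG seed.
#' @param alternative "greater" or "lower".
#' @return an `overlap_test_result`.
#' @export
similarity_test <- function(z1, occ2, background2, reps = 99, seed = 1,
                            alternative = c("greater", "lower")) {
  alternative <- match.arg(alternative)
  if (reps < 19) stopf("reps must be >= 19")
  stopifnot(inherits(z1, "niche_grid"))
  extent <- list(xlim = z1$xlim, ylim = z1$ylim)
  g2 <- density_grid(as.matrix(background2), as.matrix(occ2), R = z1$R,
                     extent = extent)
  D_obs <- schoener_d(z1, g2)
  env <- g2$env_density
  eligible <- which(env > 0, arr.ind = TRUE)
  if (nrow(eligible) < 2L) stopf("background too small for any shift")
  o <- g2$occ_density
  ci <- sum(row(o) * o) / sum(o)
  cj <- sum(col(o) * o) / sum(o)
  null <- vapply(seq_len(reps), function(r) with_seed(sub_seed(seed, r), {
    tgt <- eligible[sample.int(nrow(eligible), 1L), ]
    os <- shift_wrap(o, round(tgt[1] - ci), round(tgt[2] - cj))
    zn <- matrix(0, nrow(o), ncol(o))
    pos <- env > 0
    zn[pos] <- os[pos] / env[pos]
    if (sum(zn) == 0) return(0)
    schoener_d(z1$z, zn / sum(zn))
  }), numeric(1))
  p <- if (alternative == "greater") (sum(null >= D_obs) + 1) / (reps + 1)
       else (sum(null <= D_obs) + 1) / (reps + 1)
  overlap_test_result(D_obs, null, p, reps, alternative)
}

#' Full niche comparison between two periods
#'
#' Convenience wrapper running the PCA-env pipeline: fit the pooled PCA,
#' project backgrounds and occurrences, build the two occupancy grids on the
#' pooled background envelope, and run Schoener's D plus the equivalency and
#' similarity tests.
#'
#' @param env_bg1,env_bg2 background predictor samples for the two periods.
#' @param env_occ1,env_occ2 predictor values at each period's occurrences.
#' @param R grid resolution (default 100).
#' @param reps permutations for both tests (default 99).
#' @param seed RNG seed.
#' @return list with `pca` (`pca_env`), `grid1`, `grid2` (`niche_grid`s),
#'   `D`, `equivalency` and `similarity` (`overlap_test_result`s).
#' @export
compare_niches <- function(env_bg1, env_bg2, env_occ1, env_occ2,
                           R = 100, reps = 99, seed = 1) {
  pca <- fit_pca_env(env_bg1, env_bg2)
  b1 <- project_pca(pca, env_bg1); b2 <- project_pca(pca, env_bg2)
  o1 <- project_pca(pca, env_occ1); o2 <- project_pca(pca, env_occ2)
  bg <- rbind(b1, b2)
  extent <- list(xlim = range(bg[, 1]), ylim = range(bg[, 2]))
  g1 <- density_grid(b1, o1, R = R, extent = extent)
  g2 <- density_grid(b2, o2, R = R, extent = extent)
  eq <- equivalency_test(o1, o2, bg, reps = reps, seed = sub_seed(seed, 11),
                         R = R)
  sim <- similarity_test(g1, o2, b2, reps = reps, seed = sub_seed(seed, 13))
  list(pca = pca, grid1 = g1, grid2 = g2, D = schoener_d(g1, g2),
       equivalency = eq, similarity = sim)
}
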