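test_that("PCA-env explained variance behaves on constructed predictors", {
  set.seed(51)
  a <- rnorm(500); b <- rnorm(500)
  two_ind <- data.frame(p1 = scale(a)[, 1], p2 = scale(b)[, 1])
  p <- fit_pca_env(two_ind[1:250, ], two_ind[251:500, ])
  expect_equal(p$explained_pct, c(50, 50), tolerance = 5)
  dup <- data.frame(p1 = a, p2 = 2 * a + 1e-9 * rnorm(500))
  p2 <- fit_pca_env(dup[1:250, ], dup[251:500, ])
  expect_gt(p2$explained_pct[1], 99)
  expect_gte(p2$explained_pct[1], p2$explained_pct[2])
  expect_lte(sum(p2$explained_pct[1:2]), 100 + 1e-8)
  # loadings are orthonormal
  expect_equal(crossprod(p$rotation), diag(2), ignore_attr = TRUE)
  # constant predictor dropped with warning
  cst <- data.frame(p1 = a, p2 = b, p3 = 1)
  expect_warning(p3 <- fit_pca_env(cst[1:250, ], cst[251:500, ]), "p3")
  expect_identical(p3$predictors, c("p1", "p2"))
})

test_that("occupancy grids normalize, honor the background envelope, and locate clusters", {
  set.seed(52)
  bg <- matrix(rnorm(2000), ncol = 2)
  occ <- matrix(rnorm(100, mean = 1, sd = 0.1), ncol = 2)
  g <- density_grid(bg, occ, R = 50)
  expect_equal(sum(g$z), 1)
  expect_equal(sum(g$occ_density), 1)
  expect_equal(sum(g$env_density), 1)
  expect_true(all(g$z[g$env_density == 0] == 0))
  # argmax of z at the cluster location
  ij <- which(g$z == max(g$z), arr.ind = TRUE)[1, ]
  gx <- seq(g$xlim[1], g$xlim[2], length.out = 50)
  gy <- seq(g$ylim[1], g$ylim[2], length.out = 50)
  expect_equal(gx[ij[1]], 1, tolerance = 0.25)
  expect_equal(gy[ij[2]], 1, tolerance = 0.25)
  expect_error(density_grid(bg, occ[1:3, , drop = FALSE], R = 20), ">= 5")
  far <- occ + 100
  expect_error(density_grid(bg, far, R = 20), "envelope")
})

test_that("Schoener's D matches hand computation and its invariances", {
  z1 <- matrix(c(0.5, 0.5, 0, 0, 0, 0, 0, 0, 0), 3)
  z2 <- matrix(c(0, 0.25, 0.25, 0.25, 0.25, 0, 0, 0, 0), 3)
  # overlap only in cell 2: sum|z1-z2| = .5 + .25 + .25+.25+.25 = 1.5
  expect_equal(schoener_d(z1, z2), 0.25)
  expect_equal(schoener_d(z2, z1), 0.25)
  expect_equal(schoener_d(z1, z1), 1)
  disjoint <- matrix(c(0, 0, 0, 0, 0, 0, 0.5, 0.5, 0), 3)
  expect_equal(schoener_d(z1, disjoint), 0)
  expect_equal(schoener_d(matrix(c(1, 0)), matrix(c(0.5, 0.5))), 0.5)
  # invariance to a common cell reordering
  perm <- sample(9)
  expect_equal(schoener_d(matrix(z1[perm], 3), matrix(z2[perm], 3)),
               schoener_d(z1, z2))
  expect_warning(d <- schoener_d(2 * z1, z2), "normaliz")
  expect_equal(d, 0.25)
})

test_that("identical niches overlap fully at any grid resolution", {
  set.seed(53)
  bg <- matrix(rnorm(1000), ncol = 2)
  occ <- matrix(rnorm(60, sd = 0.5), ncol = 2)
  for (R in c(10, 100)) {
    g <- density_grid(bg, occ, R = R)
    expect_equal(schoener_d(g, g), 1)
  }
})

test_that("equivalency test: identical groups give D = 1, p = 1; output is valid and seeded", {
  set.seed(54)
  bg <- matrix(rnorm(1200), ncol = 2)
  occ <- matrix(rnorm(80, sd = 0.4), ncol = 2)
  res <- equivalency_test(occ, occ, bg, reps = 49, seed = 9, R = 40)
  expect_equal(res$D, 1)
  expect_equal(res$p_value, 1)
  occ2 <- matrix(rnorm(80, mean = 0.8, sd = 0.4), ncol = 2)
  r1 <- equivalency_test(occ, occ2, bg, reps = 49, seed = 9, R = 40)
  r2 <- equivalency_test(occ, occ2, bg, reps = 49, seed = 9, R = 40)
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_length(r1$null_distribution, 49)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_error(equivalency_test(occ[1:4, ], occ2, bg, reps = 49), ">= 5")
  expect_error(equivalency_test(occ, occ2, bg, reps = 5), ">= 19")
})

test_that("similarity test separates concentrated identical niches from random ones", {
  set.seed(55)
  bg <- matrix(runif(4000, -3, 3), ncol = 2)
  tight <- matrix(rnorm(120, sd = 0.25), ncol = 2)
  g1 <- density_grid(bg, tight, R = 40)
  same <- similarity_test(g1, tight, bg, reps = 99, seed = 10)
  expect_lt(same$p_value, 0.05)     # far more similar than chance placement
  # two tight niches at distant locations: no more similar than chance
  g_far <- density_grid(bg, matrix(rnorm(120, mean = -1.8, sd = 0.25), ncol = 2),
                        R = 40)
  rnd <- similarity_test(g_far, matrix(rnorm(120, mean = 1.8, sd = 0.25),
                                       ncol = 2), bg, reps = 99, seed = 11)
  expect_gt(rnd$p_value, 0.05)
  expect_true(all(rnd$null_distribution >= 0 & rnd$null_distribution <= 1))
})

test_that("compare_niches runs the full PCA-env pipeline coherently", {
  w <- clean_world()
  valid <- which(!is.na(w$stack$layers[[1]]))
  set.seed(56)
  bg_cells <- sample(valid, 800)
  occ_cells <- sample(valid, 60)
  env <- function(stk, cells)
    as.data.frame(lapply(stk$layers, function(m) m[cells]), optional = TRUE)
  fut <- apply_scenario(w$stack, scenario_shift(additive_deltas = c(1, 0, 0, 0, 0)))
  res <- compare_niches(env(w$stack, bg_cells), env(fut, bg_cells),
                        env(w$stack, occ_cells), env(fut, occ_cells),
                        R = 40, reps = 19, seed = 3)
  expect_gte(res$D, 0)
  expect_lte(res$D, 1)
  expect_equal(sum(res$grid1$z), 1)
  expect_gte(res$pca$explained_pct[1], res$pca$explained_pct[2])
  # identical periods -> full overlap
  res2 <- compare_niches(env(w$stack, bg_cells), env(w$stack, bg_cells),
                         env(w$stack, occ_cells), env(w$stack, occ_cells),
                         R = 30, reps = 19, seed = 4)
  expect_equal(res2$D, 1)
  expect_equal(res2$equivalency$p_value, 1)
})
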