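test_that("pseudo-absences avoid presence cells, are distinct and seeded", {
  # exhaustive 4-cell case: the 3 non-presence cells must all be drawn
  stk <- make_stack(v = matrix(0, 10, 10), cellsize = 1)
  cc <- cell_centers(stk)
  occ <- occurrence_set(data.frame(species = "sp", lon = cc$lon[1],
                                   lat = cc$lat[1]))
  pa99 <- sample_pseudo_absences(stk, occ, n = 99, seed = 1)
  expect_equal(sort(pa99$cell), setdiff(1:100, 1))
  expect_identical(sample_pseudo_absences(stk, occ, n = 50, seed = 7)$cell,
                   sample_pseudo_absences(stk, occ, n = 50, seed = 7)$cell)
  expect_error(sample_pseudo_absences(stk, occ, n = 100, seed = 1),
               "eligible")
  # large draw: all distinct, none on a presence cell
  w <- clean_world()
  pa <- w$pa
  expect_equal(anyDuplicated(pa$cell), 0)
  pres <- cell_from_lonlat(w$stack, w$occ$lon, w$occ$lat)$cell
  expect_length(intersect(pa$cell, pres), 0)
})

test_that("splits are stratified 80/20 and differ across repetitions", {
  ds <- list(y = c(rep(1L, 10), rep(0L, 10)))
  sp <- make_splits(ds, train_frac = 0.8, reps = 3, seed = 2)
  for (r in 1:3) {
    expect_equal(sum(sp[ds$y == 1, r]), 8)
    expect_equal(sum(sp[ds$y == 0, r]), 8)
  }
  expect_false(identical(sp[, 1], sp[, 2]))
  # prevalence preserved within one point at realistic imbalance
  ds2 <- list(y = c(rep(1L, 37), rep(0L, 2000)))
  sp2 <- make_splits(ds2, reps = 3, seed = 3)
  for (r in 1:3) {
    expect_equal(sum(sp2[ds2$y == 1, r]), round(0.8 * 37), tolerance = 0)
    expect_equal(sum(sp2[ds2$y == 0, r]), 1600)
  }
  expect_error(make_splits(list(y = c(1L, 0L, 0L))), ">= 2")
})

test_that("SRE recovers presence quantile envelopes and classifies by them", {
  set.seed(41)
  n <- 3000
  X <- data.frame(x1 = runif(n), x2 = runif(n))
  y <- c(rep(1L, 2500), rep(0L, 500))
  ds <- structure(list(X = X, y = y, weights = rep(1, n),
                       predictors = c("x1", "x2")), class = "modeling_dataset")
  splits <- matrix(TRUE, n, 1)
  splits[sample(n, 100), 1] <- FALSE
  m <- fit("SRE", ds, 1, splits)
  expect_false(m$failed)
  expect_lt(max(abs(m$object$lo - 0.025)), 0.015)
  expect_lt(max(abs(m$object$hi - 0.975)), 0.015)
  med <- data.frame(x1 = median(X$x1[y == 1]), x2 = median(X$x2[y == 1]))
  expect_equal(predict(m, med), 1)
  expect_setequal(unique(predict(m, X)), c(0, 1))
})

test_that("a separable problem gives GLM training AUC 1 and degenerate folds fail soft", {
  X <- data.frame(x = c(-(10:1) / 10, (1:10) / 10))
  ds <- structure(list(X = X, y = rep(c(0L, 1L), each = 10),
                       weights = rep(1, 20), predictors = "x"),
                  class = "modeling_dataset")
  splits <- matrix(rep(c(TRUE, FALSE), c(16, 4))[sample(20)], 20, 1)
  splits[, 1] <- TRUE; splits[c(1, 2, 19, 20), 1] <- FALSE
  m <- fit("GLM", ds, 1, splits)
  expect_equal(roc_auc(ds$y[splits[, 1]],
                       predict(m, ds$X[splits[, 1], , drop = FALSE])), 1)
  # all-presence training fold -> failed record, predict refuses
  degen <- matrix(c(rep(FALSE, 10), rep(TRUE, 10)), 20, 1)
  mf <- fit("GLM", ds, 1, degen)
  expect_true(mf$failed)
  expect_match(mf$reason, "single class")
  expect_error(predict(mf, X), "failed")
})

test_that("the full suite yields 9 algorithms x reps models with [0,1] scorers", {
  w <- clean_world()
  expect_length(w$suite$models, 27)
  sc <- suite_scores(w$suite)
  expect_equal(nrow(sc), 27)
  expect_setequal(unique(sc$algorithm), SDM_ALGORITHMS)
  expect_equal(unname(table(sc$repetition)), rep(9L, 3L), ignore_attr = TRUE)
  expect_false(any(sc$failed))
  set.seed(61)
  probe <- w$dataset$X[sample(nrow(w$dataset$X), 200), ]
  for (m in w$suite$models[paste0(SDM_ALGORITHMS, "_rep1")]) {
    p <- predict(m, probe)
    expect_true(all(p >= 0 & p <= 1), info = m$algorithm)
    if (m$algorithm == "SRE") expect_true(all(p %in% c(0, 1)))
  }
})

test_that("training and validation folds never overlap", {
  w <- clean_world()
  for (m in w$suite$models) {
    expect_length(intersect(m$train_idx, m$val_idx), 0)
    expect_equal(sort(c(m$train_idx, m$val_idx)), seq_along(w$dataset$y))
  }
})

test_that("reps = 1 fits one model per algorithm", {
  w <- clean_world()
  set.seed(77)
  keep <- sample(length(w$dataset$y), 400)
  keep <- keep[order(keep)]
  small <- structure(list(X = w$dataset$X[keep, ], y = w$dataset$y[keep],
                          weights = w$dataset$weights[keep],
                          predictors = w$dataset$predictors),
                     class = "modeling_dataset")
  suite1 <- fit_suite(small, reps = 1, seed = 5)
  expect_length(suite1$models, 9)
})

test_that("the SRE envelope on the driving layer contains the true optimum", {
  w <- clean_world()
  for (r in 1:3) {
    m <- w$suite$models[[paste0("SRE_rep", r)]]
    expect_lt(m$object$lo[["env_1"]], 0.5)
    expect_gt(m$object$hi[["env_1"]], 0.5)
    expect_lt(m$object$lo[["env_3"]], -0.5)
    expect_gt(m$object$hi[["env_3"]], -0.5)
  }
})
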