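test_that("committee and weighted arithmetic match hand calculations", {
  # three members voting 1, 0, 1 at a point -> committee mean 2/3 -> 667
  comm <- structure(list(method = "committee", gate = 0.8,
                         members = list(const_model(0.9, 0.9),
                                        const_model(0.2, 0.9),
                                        const_model(0.8, 0.9)),
                         weights = rep(1 / 3, 3),
                         thresholds = c(0.5, 0.5, 0.5), eval = NULL),
                    class = "sdm_ensemble")
  expect_equal(predict(comm, data.frame(x1 = 0)), 667L)
  # equal-TSS members scoring 0.2 and 0.6 -> weighted mean 0.4 -> 400
  wavg <- structure(list(method = "weighted", gate = 0.8,
                         members = list(const_model(0.2, 0.85),
                                        const_model(0.6, 0.85)),
                         weights = c(0.5, 0.5),
                         thresholds = c(0.5, 0.5), eval = NULL),
                    class = "sdm_ensemble")
  expect_equal(predict(wavg, data.frame(x1 = 0)), 400L)
})

test_that("the TSS gate keeps 0.80 and excludes 0.79", {
  models <- list(a = const_model(0.5, 0.79), b = const_model(0.5, 0.80))
  ens <- build_ensemble(models, gate = 0.8, method = "weighted")
  expect_length(ens$members, 1)
  expect_identical(ens$member_ids, "b")
  expect_equal(ens$weights, 1)
  expect_error(build_ensemble(list(a = const_model(0.5, 0.79)), gate = 0.8,
                              method = "committee"),
               "best TSS = 0.790")
})

test_that("weighted weights are TSS-proportional and sum to one", {
  models <- list(a = const_model(0.3, 0.9), b = const_model(0.7, 0.8))
  ens <- build_ensemble(models, method = "weighted")
  expect_equal(ens$weights, c(0.9, 0.8) / 1.7)
  expect_equal(sum(ens$weights), 1)
  expect_equal(predict(ens, data.frame(x1 = 0)),
               as.integer(floor(1000 * (0.3 * 0.9 + 0.7 * 0.8) / 1.7 + 0.5)))
})

test_that("ensemble grids are invariant to member ordering", {
  w <- clean_world()
  suite_rev <- w$suite
  suite_rev$models <- rev(suite_rev$models)
  probe <- w$dataset$X[1:150, ]
  for (m in c("committee", "weighted")) {
    e1 <- build_ensemble(w$suite, method = m)
    e2 <- build_ensemble(suite_rev, method = m)
    expect_equal(predict(e1, probe), predict(e2, probe))
  }
})

test_that("projection reproduces training-cell values and propagates nodata", {
  w <- clean_world()
  ens <- clean_ensembles()$committee
  proj <- project_ensemble(ens, w$stack)
  expect_equal(proj$layers[[1]][w$dataset$cell],
               as.numeric(predict(ens, w$dataset$X)))
  expect_identical(is.na(proj$layers[[1]]), is.na(w$stack$layers[[1]]))
  expect_true(all(proj$layers[[1]] >= 0 & proj$layers[[1]] <= 1000,
                  na.rm = TRUE))
  # all-nodata stack -> all-nodata output
  nastk <- raster_stack(setNames(replicate(5, matrix(NA_real_, 10, 10),
                                           simplify = FALSE),
                                 paste0("env_", 1:5)))
  expect_true(all(is.na(project_ensemble(ens, nastk)$layers[[1]])))
  expect_error(project_ensemble(ens, subset_stack(w$stack, c("env_1", "env_2"))),
               "env_3")
})

test_that("cells at the species optimum outscore cells three widths away", {
  w <- clean_world()
  at_opt <- data.frame(env_1 = 0.5, env_2 = 0, env_3 = -0.5, env_4 = 0,
                       env_5 = 0)
  off <- transform(at_opt, env_1 = 0.5 + 3 * 0.25)
  for (ens in clean_ensembles())
    expect_gt(predict(ens, at_opt), predict(ens, off))
})

test_that("pooled-validation ensemble evaluation reaches publication-grade scores", {
  for (ens in clean_ensembles()) {
    expect_gte(ens$eval$auc, 0.9)
    expect_gte(ens$eval$tss, 0.8)
    expect_equal(ens$eval$tss,
                 ens$eval$sensitivity + ens$eval$specificity - 1)
  }
})
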