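test_that("climate generator hits its cross-correlation targets", {
  # independent layers
  s0 <- climate_spec(2, c(100, 100), spatial_range = 5, seed = 3)
  stk0 <- generate_climate(s0)
  r0 <- cor(as.vector(stk0$layers[[1]]), as.vector(stk0$layers[[2]]))
  expect_lt(abs(r0), 0.1)
  # strongly correlated pair
  C <- matrix(c(1, 0.9, 0.9, 1), 2)
  s1 <- climate_spec(2, c(200, 200), spatial_range = 6,
                     cross_correlation = C, seed = 4)
  stk1 <- generate_climate(s1)
  r1 <- cor(as.vector(stk1$layers[[1]]), as.vector(stk1$layers[[2]]))
  expect_gte(r1, 0.8)
  expect_lte(r1, 1.0)
  # targets still honored under a nodata mask
  s2 <- climate_spec(3, c(100, 100), spatial_range = 5,
                     cross_correlation = matrix(c(1, .6, 0, .6, 1, 0, 0, 0, 1), 3),
                     nodata_fraction = 0.1, seed = 5)
  stk2 <- generate_climate(s2)
  X <- sapply(stk2$layers, function(m) m[!is.na(m)])
  expect_lt(max(abs(cor(X) - s2$cross_correlation)), 0.1)
})

test_that("generator output is a pure function of the spec", {
  s <- climate_spec(3, c(50, 40), spatial_range = 4, nodata_fraction = 0.05,
                    seed = 99)
  a <- generate_climate(s); b <- generate_climate(s)
  expect_identical(a$layers, b$layers)
})

test_that("invalid climate specs are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2)   # |r|>1, not PSD
  expect_error(climate_spec(2, c(20, 20), cross_correlation = bad),
               "positive semi-definite")
  expect_error(climate_spec(2, c(5, 20)), "dims >= 10")
  expect_error(climate_spec(2, c(20, 20), nodata_fraction = 1), "nodata_fraction")
  expect_error(climate_spec(2, c(20, 20),
                            cross_correlation = matrix(c(1, .2, .3, 1), 2)),
               "symmetric")
})

test_that("true suitability is the rescaled product of Gaussian responses", {
  a <- matrix(0, 10, 10); b <- matrix(0, 10, 10)
  a[1, 1] <- 0; a[2, 2] <- 3 * 0.5      # 3 widths from the optimum
  stk <- make_stack(a = a, b = b)
  sp <- virtual_species(c("a", "b"), c(0, 0), c(0.5, 1))
  suit <- true_suitability(stk, sp)
  expect_equal(suit$layers[[1]][1, 1], 1.0)          # at both optima
  expect_equal(suit$layers[[1]][2, 2], exp(-4.5))    # 3 sd on one axis
  # a non-driving layer has no effect
  stk2 <- make_stack(a = a, b = b, c = matrix(rnorm(100), 10, 10))
  expect_equal(true_suitability(stk2, sp)$layers[[1]], suit$layers[[1]])
  # all-nodata stack errors
  stk3 <- make_stack(a = matrix(NA_real_, 10, 10), b = matrix(NA_real_, 10, 10))
  expect_error(true_suitability(stk3, sp), "no valid cells")
})

test_that("occurrence sampling respects suitability and cell uniqueness", {
  u <- matrix(1, 10, 10)
  suit <- make_stack(suitability = u)
  occ <- sample_occurrences(suit, 10, seed = 1)
  expect_equal(nrow(occ), 10)
  expect_equal(nrow(unique(occ[, c("lon", "lat")])), 10)
  # single positive cell
  z <- matrix(0, 10, 10); z[4, 7] <- 1
  occ1 <- sample_occurrences(make_stack(suitability = z), 1, seed = 2)
  cc <- cell_centers(make_stack(suitability = z))
  expect_equal(c(occ1$lon, occ1$lat), c(cc$lon[cc$cell == 64], cc$lat[cc$cell == 64]))
  # zero-suitability half never sampled
  h <- matrix(0, 10, 20); h[, 1:10] <- 1
  stk <- make_stack(suitability = h)
  occ2 <- sample_occurrences(stk, 80, seed = 3)
  vals <- extract_values(stk, occ2$lon, occ2$lat)$suitability
  expect_true(all(vals == 1))
  # more draws than positive cells errors
  expect_error(sample_occurrences(make_stack(suitability = z), 2), "exceeds")
})

test_that("scenario shifts are exact affine maps that conserve the mask", {
  w <- clean_world()
  ident <- apply_scenario(w$stack, scenario_shift())
  expect_equal(ident$layers, w$stack$layers)
  sh <- apply_scenario(w$stack, scenario_shift(additive_deltas = c(2, 0, 0, 0, 0)))
  expect_equal(mean(sh$layers$env_1, na.rm = TRUE),
               mean(w$stack$layers$env_1, na.rm = TRUE) + 2)
  expect_identical(is.na(sh$layers$env_1), is.na(w$stack$layers$env_1))
  expect_error(apply_scenario(w$stack, scenario_shift(additive_deltas = c(1, 2))),
               "n_layers")
  expect_error(scenario_shift(multiplicative_deltas = 0), "> 0")
})

test_that("a shift away from the optimum strictly shrinks the true suitable area", {
  w <- clean_world()
  fut <- apply_scenario(w$stack, scenario_shift(additive_deltas = c(3, 0, 0, 0, 0)))
  s_now <- true_suitability(w$stack, w$species)$layers[[1]]
  s_fut <- true_suitability(fut, w$species)$layers[[1]]
  expect_lt(sum(s_fut > 0.5, na.rm = TRUE), sum(s_now > 0.5, na.rm = TRUE))
})

test_that("sampled presences concentrate in the top suitability quantile", {
  w <- clean_world()
  p <- w$species$prevalence_target
  s <- w$suit$layers[[1]]
  qtop <- quantile(s[!is.na(s)], 1 - p)
  vals <- extract_values(w$suit, w$occ$lon, w$occ$lat)$suitability
  expect_gte(mean(vals >= qtop), 2 * p)
})
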