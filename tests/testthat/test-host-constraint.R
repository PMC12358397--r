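test_that("the conditional probability transfer applies the threshold rule", {
  p_ha <- as_layer(matrix(c(0.5, 0.4, 0.39, 0.1), 2, 2, byrow = TRUE))
  p_cd <- as_layer(matrix(c(0.8, 0.2, 0.9, 0.7), 2, 2, byrow = TRUE))
  out <- conditional_probability_transfer(p_cd, p_ha, 0.4)
  expect_equal(out$values, matrix(c(0.8, 0.2, 0, 0), 2, 2, byrow = TRUE))
  # all-below -> zero layer; all-at-or-above -> identity
  lo <- as_layer(matrix(0.1, 2, 2))
  hi <- as_layer(matrix(0.9, 2, 2))
  expect_true(all(conditional_probability_transfer(p_cd, lo)$values == 0))
  expect_equal(conditional_probability_transfer(p_cd, hi)$values, p_cd$values)
  expect_error(conditional_probability_transfer(p_cd, p_ha, 1), "theta")
})

test_that("the transfer is idempotent and propagates nodata", {
  set.seed(31)
  p_cd <- as_layer(matrix(runif(100), 10, 10))
  ha <- matrix(runif(100), 10, 10); ha[1, 1] <- NA
  p_ha <- as_layer(ha)
  once <- conditional_probability_transfer(p_cd, p_ha)
  twice <- conditional_probability_transfer(once, p_ha)
  expect_equal(once$values, twice$values)
  expect_true(is.na(once$values[1, 1]))
})

test_that("constrained suitable cells are a subset of host-suitable cells", {
  set.seed(32)
  p_cd <- as_layer(matrix(runif(400), 20, 20))
  p_ha <- as_layer(matrix(runif(400), 20, 20))
  out <- conditional_probability_transfer(p_cd, p_ha, 0.4)
  suitable <- binarize(out, 0.4)$values == 1
  expect_true(all(p_ha$values[suitable] >= 0.4))
})

test_that("area difference rates implement the published formula", {
  # current high- and medium-suitability class areas, PCS vs NHS
  expect_equal(area_difference_rate(23.88, 26.92), -11.29, tolerance = 5e-4)
  expect_equal(area_difference_rate(46.02, 47.19), -2.48, tolerance = 2e-3)
  expect_equal(area_difference_rate(5, 5), 0)
  expect_true(is.na(suppressWarnings(area_difference_rate(1, 0))))
  expect_warning(area_difference_rate(1, 0), "zero")
  # monotone increasing in the PCS area
  r <- area_difference_rate(c(1, 2, 3), 2)
  expect_true(all(diff(r) > 0))
})

test_that("the PCS predictor stack appends host suitability", {
  tpl <- grid_template(10, 10)
  env <- generate_env_layers(tpl, 3, smoothness = 2, seed = 33)
  ha <- env[[1]]
  ha$values[4, 4] <- NA
  stack <- build_pcs_predictors(env, ha)
  expect_length(stack, 4)
  expect_named(stack, c("env1", "env2", "env3", "P_HA"))
  # host nodata propagates into every layer of the stack
  expect_true(all(vapply(stack, function(g) is.na(g$values[4, 4]), TRUE)))
})

test_that("degenerate host layers bound the two-scenario comparison", {
  s <- synthetic_study(nrows = 50, ncols = 50, n_host = 80, n_parasite = 60,
                       seed = 41)
  # host everywhere suitable: the transfer never bites
  ones <- grid_layer(matrix(1, 50, 50), s$env[[1]]$xll, s$env[[1]]$yll,
                     s$env[[1]]$cellsize)
  cmp1 <- suppressWarnings(run_two_scenarios(s$parasite_occ, s$env, ones,
                            spec = feature_spec("lq"), rm = 1,
                            n_replicates = 2, n_background = 800,
                            seed = 42))
  # with host == 1 the constrained layer equals the unmasked PCS prediction
  expect_true(all(cmp1$layers$p_pcs$values > 0))
  # host nowhere suitable: all PCS area zero, rates -100%
  zeros <- grid_layer(matrix(0, 50, 50), s$env[[1]]$xll, s$env[[1]]$yll,
                      s$env[[1]]$cellsize)
  cmp0 <- suppressWarnings(run_two_scenarios(s$parasite_occ, s$env, zeros,
                            spec = feature_spec("lq"), rm = 1,
                            n_replicates = 2, n_background = 800,
                            seed = 43))
  suit <- cmp0$class_areas[cmp0$class_areas$label == "suitable", ]
  expect_equal(suit$pcs_km2, 0)
  expect_equal(suit$difference_rate, -100)
  expect_true(all(cmp0$layers$p_pcs$values == 0))
})

test_that("the full two-scenario run honours the subset invariant", {
  s <- synthetic_study(nrows = 60, ncols = 60, n_host = 120, n_parasite = 80,
                       seed = 51)
  cmp <- run_two_scenarios(s$parasite_occ, s$env, s$host_occ,
                           spec = feature_spec("lq"), rm = 1,
                           host_spec = feature_spec("lq"), host_rm = 1,
                           n_replicates = 2, n_background = 1000, seed = 52)
  suitable <- binarize(cmp$layers$p_pcs, 0.4)$values == 1
  expect_true(all(cmp$layers$p_ha$values[suitable] >= 0.4))
  # difference rate column is consistent with the stored areas
  t <- cmp$class_areas
  ok <- t$nhs_km2 > 0
  expect_equal(t$difference_rate[ok],
               (t$pcs_km2[ok] - t$nhs_km2[ok]) / t$nhs_km2[ok] * 100)
})
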