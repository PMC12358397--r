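test_that("synthetic environments hit their correlation targets", {
  tpl <- grid_template(100, 100)
  # uncorrelated pair
  e0 <- generate_env_layers(tpl, 2, smoothness = 0, pairwise_r = 0, seed = 61)
  r0 <- cor(as.vector(e0[[1]]$values), as.vector(e0[[2]]$values))
  expect_lt(abs(r0), 0.1)
  # correlated pair: realized r within 0.1 of target at 10^4 cells
  e7 <- generate_env_layers(tpl, 2, smoothness = 0, pairwise_r = 0.7, seed = 62)
  r7 <- cor(as.vector(e7[[1]]$values), as.vector(e7[[2]]$values))
  expect_lt(abs(r7 - 0.7), 0.1)
  # white noise at smoothness 0: negligible lag-1 autocorrelation
  v <- e0[[1]]$values
  lag1 <- cor(as.vector(v[, -1]), as.vector(v[, -ncol(v)]))
  expect_lt(abs(lag1), 0.1)
  # smoothing induces strong lag-1 autocorrelation
  es <- generate_env_layers(tpl, 1, smoothness = 5, seed = 63)
  vs <- es[[1]]$values
  lag1s <- cor(as.vector(vs[, -1]), as.vector(vs[, -ncol(vs)]))
  expect_gt(lag1s, 0.8)
  # determinism and range
  e0b <- generate_env_layers(tpl, 2, smoothness = 0, pairwise_r = 0, seed = 61)
  expect_identical(e0, e0b)
  expect_true(all(vapply(e0, function(g) all(g$values >= 0 & g$values <= 1),
                         TRUE)))
})

test_that("virtual species respond as configured", {
  tpl <- grid_template(30, 30)
  env <- generate_env_layers(tpl, 2, smoothness = 3, seed = 64)
  # all-zero coefficients: truth is constant inverse-logit(intercept)
  flat <- make_virtual_species(env, intercept = 1)
  expect_true(all(flat$truth$values == plogis(1)))
  # strong positive coefficient: truth rank-correlates with the layer
  inc <- make_virtual_species(env, linear = c(env1 = 10), intercept = -5)
  rho <- cor(as.vector(env$env1$values), as.vector(inc$truth$values),
             method = "spearman")
  expect_gt(rho, 0.9)
  # quadratic-only species peaks at the configured optimum
  u <- seq(0, 1, 0.01)
  peak <- make_virtual_species(env, linear = c(env1 = 44),
                               quadratic = c(env1 = -40), intercept = -9.1)
  eta <- function(x) -9.1 + 44 * x - 40 * x^2
  expect_equal(u[which.max(eta(u))], 0.55)  # optimum of the response
  cell_at_peak <- which.min(abs(env$env1$values - 0.55))
  expect_gte(peak$truth$values[cell_at_peak],
             max(peak$truth$values) - 1e-6)
  expect_error(make_virtual_species(env, linear = c(nope = 1)), "absent")
})

test_that("parasite truth is the env response masked by host truth", {
  tpl <- grid_template(30, 30)
  env <- generate_env_layers(tpl, 3, smoothness = 3, seed = 65)
  host <- make_virtual_species(env, linear = c(env1 = 8), intercept = -4)
  par <- make_parasite(host, env, linear = c(env2 = 6), intercept = -2,
                       theta_true = 0.4)
  env_resp <- make_virtual_species(env, linear = c(env2 = 6), intercept = -2)
  # zero exactly where host truth < 0.4, env response elsewhere
  below <- host$truth$values < 0.4
  expect_true(all(par$truth$values[below] == 0))
  expect_equal(par$truth$values[!below], env_resp$truth$values[!below])
  expect_equal(mean(par$truth$values == 0), mean(below))
  # degenerate hosts
  ones <- make_virtual_species(env, intercept = 50)
  par1 <- make_parasite(ones, env, linear = c(env2 = 6), intercept = -2)
  expect_equal(par1$truth$values, env_resp$truth$values)
  zeros <- make_virtual_species(env, intercept = -50)
  par0 <- make_parasite(zeros, env, linear = c(env2 = 6), intercept = -2)
  expect_true(all(par0$truth$values == 0))
})

test_that("occurrence sampling follows the truth intensity", {
  tpl <- grid_template(5, 5)
  one <- grid_layer(matrix(c(1, rep(0, 24)), 5, 5), tpl$xll, tpl$yll,
                    tpl$cellsize)
  sp1 <- structure(list(truth = one), class = "virtual_species")
  occ1 <- sample_occurrences(sp1, 1, seed = 66)
  cc <- cell_centers(one)
  expect_equal(occ1$lon, cc$lon[1])
  expect_equal(occ1$lat, cc$lat[1])
  # uniform truth: per-cell frequencies within binomial 3 sigma
  unif <- structure(list(truth = grid_layer(matrix(1, 10, 10), 0, 0, 0.1)),
                    class = "virtual_species")
  counts <- integer(100)
  for (sd_ in 1:200) {
    occ <- sample_occurrences(unif, 10, seed = sd_)
    cells <- locate_cells(unif$truth, occ$lon, occ$lat)
    counts[(cells$row - 1) * 10 + cells$col] <-
      counts[(cells$row - 1) * 10 + cells$col] + 1L
  }
  p <- 10 / 100
  # 4-sigma band: with 100 simultaneous cells a 3-sigma band would flag
  # ordinary binomial fluctuation too often
  expect_true(all(abs(counts - 200 * p) <= 4 * sqrt(200 * p * (1 - p))))
  # reproducible; capped by available cells
  expect_identical(sample_occurrences(unif, 10, seed = 1),
                   sample_occurrences(unif, 10, seed = 1))
  expect_error(sample_occurrences(sp1, 2, seed = 1), "without replacement")
})
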