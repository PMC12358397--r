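test_that("null data give the null model: uniform raw output", {
  set.seed(2)
  bg <- data.frame(x = runif(400), y = runif(400))
  m <- maxent(bg, bg, feature_spec("lq"), rm = 1)  # presence dist == background
  raw <- predict(m, bg, type = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  expect_lt(max(abs(raw - 1 / 400)), 1e-8 / 400)
  expect_lt(sum(abs(coef(m))), 1e-8)
})

test_that("1-D fit matches an independent line-search of the same objective", {
  set.seed(5)
  ub <- runif(500)
  # presences biased toward high x
  up <- ub[sample(500, 120, prob = ub^2, replace = TRUE)]
  m <- maxent(data.frame(x = up), data.frame(x = ub), feature_spec("l"), rm = 1)
  # the model works on the background-scaled feature u = (x - min) / range
  fb <- (ub - min(ub)) / diff(range(ub))
  fp <- pmin(pmax((up - min(ub)) / diff(range(ub)), 0), 1)
  beta <- m$beta
  obj <- function(l) mean(fp) * l - log(sum(exp(l * fb))) - beta * abs(l)
  oracle <- stats::optimize(obj, c(-100, 100), maximum = TRUE,
                            tol = 1e-10)$maximum
  expect_equal(unname(coef(m)), oracle, tolerance = 1e-4)
})

test_that("a huge regularization multiplier empties the model", {
  set.seed(6)
  bg <- data.frame(x = runif(300))
  pres <- data.frame(x = runif(50, 0.5, 1))
  m <- maxent(pres, bg, feature_spec("lq"), rm = 1e6)
  expect_equal(m$k_nonzero, 0)
})

test_that("penalized objective is monotone and beats the null model", {
  s <- small_system()
  occ <- sample_occurrences(s$species, 100, seed = 2)
  bg <- sample_background(valid_mask(s$env), 1500, seed = 3)
  m <- maxent(extract_values(s$env, occ$lon, occ$lat),
              extract_values(s$env, bg$lon, bg$lat), feature_spec("lq"), 1)
  expect_true(all(diff(m$objective) >= -1e-9))
  # objective at lambda = 0 is -log(n_background)
  expect_gte(utils::tail(m$objective, 1), -log(m$n_background) - 1e-7)
  expect_gte(m$entropy, 0)
  expect_lte(m$k_nonzero, length(coef(m)))
})

test_that("logistic output is the entropy transform of raw and monotone in it", {
  s <- small_system(seed = 21)
  occ <- sample_occurrences(s$species, 80, seed = 4)
  bg <- sample_background(valid_mask(s$env), 1000, seed = 5)
  bgd <- extract_values(s$env, bg$lon, bg$lat)
  m <- maxent(extract_values(s$env, occ$lon, occ$lat), bgd,
              feature_spec("lq"), 1)
  raw <- predict(m, bgd, type = "raw")
  p <- predict(m, bgd, type = "logistic")
  expect_true(all(p > 0 & p < 1))
  expect_equal(p, exp(m$entropy) * raw / (1 + exp(m$entropy) * raw))
  expect_equal(order(p), order(raw))  # monotone rescaling
  # raw = exp(-H) maps to 0.5 exactly (checked via the transform itself)
  er <- exp(m$entropy) * exp(-m$entropy)
  expect_equal(er / (1 + er), 0.5)
})

test_that("fitted ranking recovers a known linear+quadratic truth", {
  tpl <- grid_template(60, 60)
  env <- generate_env_layers(tpl, 2, smoothness = 5, seed = 31)
  sp <- anchored_species(env, "env1", b = 10, b0 = 2)
  occ <- sample_occurrences(sp, 200, seed = 32)
  bg <- sample_background(valid_mask(env), 2000, seed = 33)
  m <- maxent(extract_values(env, occ$lon, occ$lat),
              extract_values(env, bg$lon, bg$lat), feature_spec("lq"), 1)
  pred <- predict(m, env, type = "logistic")
  rho <- cor(as.vector(sp$truth$values), as.vector(pred$values),
             method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("AUC is high on strong signal and near 0.5 on noise", {
  tpl <- grid_template(40, 40)
  env41 <- generate_env_layers(tpl, 2, smoothness = 4, seed = 41)
  s <- list(env = env41,
            species = anchored_species(env41, "env1", b = 150, b0 = 3))
  occ <- sample_occurrences(s$species, 120, seed = 42)
  sp_split <- split_presences(occ, 0.25, seed = 43)
  bg <- sample_background(valid_mask(s$env), 1500, seed = 44)
  bgd <- extract_values(s$env, bg$lon, bg$lat)
  m <- maxent(extract_values(s$env, sp_split$train$lon, sp_split$train$lat),
              bgd, feature_spec("lq"), 1)
  auc_strong <- auc_mw(
    predict(m, extract_values(s$env, sp_split$test$lon, sp_split$test$lat),
            type = "raw"),
    predict(m, bgd, type = "raw"))
  expect_gte(auc_strong, 0.9)
  # signal-free: presences uniform over the landscape
  unif <- make_virtual_species(s$env, intercept = 0)
  occ0 <- sample_occurrences(unif, 200, seed = 45)
  m0 <- maxent(extract_values(s$env, occ0$lon, occ0$lat), bgd,
               feature_spec("lq"), 1)
  auc0 <- auc_mw(predict(m0, extract_values(s$env, occ0$lon, occ0$lat),
                         type = "raw"),
                 predict(m0, bgd, type = "raw"))
  expect_lt(abs(auc0 - 0.5), 0.05)
})

test_that("serialized models reload and predict identically", {
  s <- small_system(seed = 51)
  occ <- sample_occurrences(s$species, 60, seed = 52)
  bg <- sample_background(valid_mask(s$env), 800, seed = 53)
  bgd <- extract_values(s$env, bg$lon, bg$lat)
  m <- maxent(extract_values(s$env, occ$lon, occ$lat), bgd,
              feature_spec("lqh", hinge_knots = 10), 1.5)
  f <- withr::local_tempfile(fileext = ".model")
  write_maxent(m, f)
  m2 <- read_maxent(f)
  expect_equal(coef(m2), coef(m))
  expect_equal(predict(m2, bgd, type = "logistic"),
               predict(m, bgd, type = "logistic"))
  expect_equal(m2$entropy, m$entropy)
})

test_that("background sampling is reproducible, uniform, and caps at all cells", {
  mask <- grid_layer(matrix(1, 10, 10), 0, 0, 1, kind = "binary")
  s1 <- sample_background(mask, 30, seed = 7)
  s2 <- sample_background(mask, 30, seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(sample_background(mask, 1000, seed = 7)), 100)
  # frequency of one fixed cell over many seeds ~ Binomial(n, 30/100), 3 sigma
  hits <- sum(vapply(1:150, function(sd)
    any(sample_background(mask, 30, seed = sd)$row == 5 &
          sample_background(mask, 30, seed = sd)$col == 5), TRUE))
  p <- 30 / 100
  expect_lt(abs(hits - 150 * p), 3 * sqrt(150 * p * (1 - p)))
})

test_that("simulate draws cells in proportion to the fitted density", {
  set.seed(8)
  bg <- data.frame(x = c(rep(0.1, 5), rep(0.9, 5)))
  pres <- data.frame(x = runif(40, 0.6, 1))
  m <- maxent(pres, bg, feature_spec("l"), rm = 0.5)
  sim <- simulate(m, nsim = 2, seed = 9, newdata = bg, size = 2000)
  raw <- predict(m, bg, type = "raw")
  frac_high <- mean(unlist(sim) > 5)  # rows 6-10 are the high-x cells
  expect_equal(frac_high, sum(raw[6:10]), tolerance = 0.05)
})
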