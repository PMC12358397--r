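test_that("classification boundaries follow the printed half-open bins", {
  p <- as_layer(matrix(c(0, 0.1999, 0.2, 0.3999, 0.4, 0.5999, 0.6, 1), 2, 4))
  cl <- classify_suitability(p)
  expect_equal(as.vector(cl$values), c(0, 0, 1, 1, 2, 2, 3, 3))
  # named boundary cases
  one <- function(x) classify_suitability(as_layer(matrix(x, 1, 1)))$values[1, 1]
  expect_equal(one(0.2), 1)  # low starts at exactly 0.2
  expect_equal(one(0.4), 2)  # medium starts at exactly 0.4
  expect_equal(one(0.6), 3)  # high starts at exactly 0.6
  expect_error(classify_suitability(p, breaks = c(0.4, 0.2, 0.6)))
})

test_that("binarization cuts at 0.4 and agrees with the class map", {
  one <- function(x) binarize(as_layer(matrix(x, 1, 1)))$values[1, 1]
  expect_equal(one(0.4), 1)
  expect_equal(one(0.3999), 0)
  set.seed(21)
  p <- as_layer(matrix(runif(900), 30, 30))
  cl <- classify_suitability(p)
  b <- binarize(p, 0.4)
  expect_equal(b$values, (cl$values >= 2) * 1)  # medium-or-high == suitable
})

test_that("per-class areas match brute-force masked sums", {
  set.seed(22)
  cl <- as_layer(matrix(sample(0:3, 600, replace = TRUE), 20, 30),
                 kind = "class4")
  areas <- cell_area_layer(cl)
  tab <- class_areas(cl, areas)
  for (k in 0:3) {
    brute <- sum(areas$values[cl$values == k])
    expect_equal(tab$area_km2[tab$class == k], brute)
  }
  expect_equal(sum(tab$area_km2), sum(areas$values))
  expect_equal(tab$area_1e4_km2, tab$area_km2 / 1e4)
})

test_that("change maps enumerate the four binary transitions", {
  set.seed(23)
  b1 <- as_layer(matrix(rbinom(9, 1, 0.5), 3, 3), kind = "binary")
  b2 <- as_layer(matrix(rbinom(9, 1, 0.5), 3, 3), kind = "binary")
  areas <- cell_area_layer(b1)
  ch <- change_map(b1, b2, areas)
  for (i in 1:3) for (j in 1:3) {
    code <- b1$values[i, j] * 2 + b2$values[i, j]
    expect_equal(ch$map$values[i, j], code)
  }
  expect_equal(sum(ch$areas$area_km2), sum(areas$values))  # partition
  same <- change_map(b1, b1, areas)
  expect_equal(same$areas$area_km2[same$areas$category == "expansion"], 0)
  expect_equal(same$areas$area_km2[same$areas$category == "contraction"], 0)
  comp <- as_layer(1 - b1$values, kind = "binary")
  flip <- change_map(b1, comp, areas)
  expect_equal(flip$areas$area_km2[flip$areas$category == "stable_suitable"], 0)
  expect_equal(flip$areas$area_km2[flip$areas$category == "stable_unsuitable"], 0)
})

test_that("centroids are area-weighted cell-center means", {
  # single suitable cell -> its center
  m <- matrix(0, 4, 4); m[2, 3] <- 1
  b <- as_layer(m, kind = "binary", xll = 10, yll = 50, cs = 1)
  areas <- cell_area_layer(b)
  cen <- suitable_centroid(b, areas)
  expect_equal(unname(cen), c(10 + 2.5, 50 + 2.5))
  # symmetry about a meridian
  m2 <- matrix(0, 3, 4); m2[2, 2] <- 1; m2[2, 3] <- 1
  b2 <- as_layer(m2, kind = "binary", xll = 0, yll = 0, cs = 1)
  cen2 <- suitable_centroid(b2, cell_area_layer(b2))
  expect_equal(unname(cen2["lon"]), 2)  # midway between columns 2 and 3
  # random mask matches a direct weighted mean
  set.seed(24)
  m3 <- matrix(rbinom(200, 1, 0.4), 10, 20)
  b3 <- as_layer(m3, kind = "binary", xll = 70, yll = 20, cs = 0.5)
  a3 <- cell_area_layer(b3)
  cen3 <- suitable_centroid(b3, a3)
  cc <- cell_centers(b3)
  idx <- which(m3 == 1, arr.ind = TRUE)
  w <- a3$values[idx]
  expect_equal(unname(cen3["lon"]), sum(w * cc$lon[idx[, 2]]) / sum(w))
  expect_equal(unname(cen3["lat"]), sum(w * cc$lat[idx[, 1]]) / sum(w))
  expect_error(suitable_centroid(as_layer(matrix(0, 2, 2), kind = "binary"),
                                 cell_area_layer(as_layer(matrix(0, 2, 2)))),
               "no suitable cell")
})

test_that("centroid shifts follow the haversine closed form", {
  expect_equal(unname(centroid_shift(c(100, 40), c(100, 40))["distance_km"]), 0)
  # one degree of latitude on the authalic sphere
  d <- centroid_shift(c(100, 40), c(100, 41))
  expect_equal(unname(d["distance_km"]), 111.19, tolerance = 0.0001)
  expect_equal(unname(d["bearing_deg"]), 0)
  # symmetric in distance, antipodal in bearing
  d2 <- centroid_shift(c(100, 41), c(100, 40))
  expect_equal(unname(d2["distance_km"]), unname(d["distance_km"]))
  expect_equal(unname(d2["bearing_deg"]), 180)
  # triangle inequality along a path
  a <- c(90, 35); b <- c(93, 37); c3 <- c(95, 40)
  expect_gte(centroid_shift(a, b)["distance_km"] +
               centroid_shift(b, c3)["distance_km"],
             centroid_shift(a, c3)["distance_km"])
})
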