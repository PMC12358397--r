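#' Four-level suitability classification
#'
#' Bins a suitability layer `P` into 0 = unsuitable (`P < b1`), 1 = low
#' (`b1 <= P < b2`), 2 = medium (`b2 <= P < b3`), 3 = high (`P >= b3`) with
#' the default breaks 0.2 / 0.4 / 0.6. Nodata propagates.
#'
#' @param p continuous `grid_layer` with values in [0, 1].
#' @param breaks strictly increasing vector of three breaks in (0, 1).
#' @return `class4` `grid_layer` (codes 0-3).
#' @export
classify_suitability <- function(p, breaks = c(0.2, 0.4, 0.6)) {
  stopifnot(length(breaks) == 3, all(diff(breaks) > 0),
            all(breaks > 0 & breaks < 1))
  v <- p$values
  cl <- (v >= breaks[1]) + (v >= breaks[2]) + (v >= breaks[3])
  grid_layer(cl, p$xll, p$yll, p$cellsize, p$nodata_value, "class4")
}

#' Suitability class labels
#' @return character vector naming codes 0-3.
#' @export
class4_labels <- function() c("unsuitable", "low", "medium", "high")

#' Per-class areas of a classified layer
#'
#' @param classes `class4` (or categorical/binary) `grid_layer`.
#' @param cell_areas co-registered per-cell area layer (km2), see
#'   [cell_area_layer()].
#' @param labels optional names for the codes present.
#' @return data.frame with `class` (code), `label`, `area_km2`,
#'   `area_1e4_km2`.
#' @export
class_areas <- function(classes, cell_areas, labels = NULL) {
  assert_coregistered(list(classes, cell_areas))
  ok <- is.finite(classes$values)
  codes <- sort(unique(classes$values[ok]))
  area <- vapply(codes, function(k)
    sum(cell_areas$values[ok & classes$values == k]), 0)
  if (is.null(labels) && classes$kind == "class4") labels <- class4_labels()
  lab <- if (is.null(labels)) as.character(codes) else labels[codes + 1]
  data.frame(class = codes, label = lab, area_km2 = area,
             area_1e4_km2 = area / 1e4, stringsAsFactors = FALSE)
}

#' Binary suitable/unsuitable layer
#'
#' 1 where `P >= theta`, 0 where `P < theta` (default theta 0.4, the
#' medium-or-high cut). Nodata propagates.
#'
#' @param p continuous `grid_layer`.
#' @param theta threshold in (0, 1).
#' @return binary `grid_layer`.
#' @export
binarize <- function(p, theta = 0.4) {
  stopifnot(theta > 0, theta < 1)
  grid_layer((p$values >= theta) * 1, p$xll, p$yll, p$cellsize,
             p$nodata_value, "binary")
}

#' Change map between two binary suitability layers
#'
#' Codes: 0 = stable unsuitable (0-0), 1 = expansion (0-1), 2 = contraction
#' (1-0), 3 = stable suitable (1-1). The four category areas partition the
#' jointly valid area.
#'
#' @param bin_t1,bin_t2 co-registered binary `grid_layer`s (earlier, later).
#' @param cell_areas co-registered area layer (km2).
#' @return list: `map` (`class4` layer with the codes above), `areas`
#'   (data.frame category, code, area_km2, area_1e4_km2).
#' @export
change_map <- function(bin_t1, bin_t2, cell_areas) {
  assert_coregistered(list(bin_t1, bin_t2, cell_areas))
  code <- bin_t1$values * 2 + bin_t2$values  # 0-0->0, 0-1->1, 1-0->2, 1-1->3
  map <- grid_layer(code, bin_t1$xll, bin_t1$yll, bin_t1$cellsize,
                    bin_t1$nodata_value, "class4")
  ok <- is.finite(code)
  area <- vapply(0:3, function(k) sum(cell_areas$values[ok & code == k]), 0)
  list(map = map,
       areas = data.frame(
         category = c("stable_unsuitable", "expansion", "contraction",
                      "stable_suitable"),
         code = 0:3, area_km2 = area, area_1e4_km2 = area / 1e4,
         stringsAsFactors = FALSE))
}

#' Area-weighted centroid of the suitable region
#'
#' Mean of suitable-cell center coordinates weighted by spherical cell
#' area. Longitude averaging assumes the region does not span the
#' antimeridian (error if suitable longitudes span more than 180 degrees).
#'
#' @param bin binary `grid_layer` with >= 1 suitable cell.
#' @param cell_areas co-registered area layer.
#' @return named numeric vector `c(lon, lat)`.
#' @export
suitable_centroid <- function(bin, cell_areas) {
  assert_coregistered(list(bin, cell_areas))
  idx <- which(is.finite(bin$values) & bin$values == 1, arr.ind = TRUE)
  if (!nrow(idx)) stop("no suitable cell; centroid undefined")
  cc <- cell_centers(bin)
  lon <- cc$lon[idx[, 2]]; lat <- cc$lat[idx[, 1]]
  if (max(lon) - min(lon) > 180)
    stop("suitable region spans the antimeridian; centroid not supported")
  w <- cell_areas$values[idx]
  c(lon = sum(w * lon) / sum(w), lat = sum(w * lat) / sum(w))
}

#' Great-circle shift between two centroids
#'
#' Haversine distance on a sphere of authalic radius 6371.0072 km and the
#' initial bearing from the first point, in [0, 360).
#'
#' @param c1,c2 numeric `c(lon, lat)` vectors (degrees).
#' @return named vector `c(distance_km, bearing_deg)`.
#' @export
centroid_shift <- function(c1, c2) {
  stopifnot(length(c1) == 2, length(c2) == 2,
            all(is.finite(c(c1, c2))), abs(c1[2]) <= 90, abs(c2[2]) <= 90)
  d <- geosphere::distHaversine(unname(c1), unname(c2), r = 6371.0072)
  b <- if (d == 0) 0 else geosphere::bearing(unname(c1), unname(c2)) %% 360
  c(distance_km = d, bearing_deg = b)
}
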