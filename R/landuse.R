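#' Categorical land-use layer with a code table
#'
#' @param grid integer-coded categorical `grid_layer`.
#' @param codes named integer vector mapping class names to codes, default
#'   the six-type scheme Cropland/Forest/Grassland/Urban/Unused/Water = 1:6.
#' @return A `land_use_layer`.
#' @export
land_use_layer <- function(grid,
                           codes = c(Cropland = 1, Forest = 2, Grassland = 3,
                                     Urban = 4, Unused = 5, Water = 6)) {
  stopifnot(inherits(grid, "grid_layer"))
  v <- grid$values[is.finite(grid$values)]
  if (!all(v %in% codes))
    stop("land-use layer contains codes missing from the code table")
  g <- grid_layer(grid$values, grid$xll, grid$yll, grid$cellsize,
                  grid$nodata_value, "categorical")
  structure(list(grid = g, codes = codes), class = "land_use_layer")
}

#' @export
print.land_use_layer <- function(x, ...) {
  cat("<land_use_layer>", paste(names(x$codes), x$codes, sep = "=",
                                collapse = ", "), "\n")
  print(x$grid)
  invisible(x)
}

#' Intersection of binary suitable layers across periods
#'
#' A cell is stable suitable iff it is suitable (1) in **every** input
#' layer. Commutative and associative; nodata propagates.
#'
#' @param bin_layers list of >= 2 co-registered binary `grid_layer`s.
#' @return binary `grid_layer`.
#' @export
stable_suitable <- function(bin_layers) {
  stopifnot(length(bin_layers) >= 2)
  assert_coregistered(bin_layers)
  v <- Reduce(`*`, lapply(bin_layers, function(g) g$values))
  g <- bin_layers[[1]]
  grid_layer(v, g$xll, g$yll, g$cellsize, g$nodata_value, "binary")
}

#' Land-use composition of the stable suitable area
#'
#' Per-class area inside `stable == 1` cells and its percentage of the
#' stable area; percentages sum to 100 over represented classes. An empty
#' stable mask yields zero areas with a warning.
#'
#' @param stable binary `grid_layer`.
#' @param lu a `land_use_layer`.
#' @param cell_areas co-registered area layer (km2).
#' @return data.frame with `class`, `code`, `area_km2`, `percent`.
#' @export
landuse_composition <- function(stable, lu, cell_areas) {
  assert_coregistered(list(stable, lu$grid, cell_areas))
  inside <- is.finite(stable$values) & stable$values == 1 &
    is.finite(lu$grid$values)
  area <- vapply(lu$codes, function(k)
    sum(cell_areas$values[inside & lu$grid$values == k]), 0)
  tot <- sum(area)
  if (tot == 0) warning("stable suitable mask is empty")
  data.frame(class = names(lu$codes), code = unname(lu$codes),
             area_km2 = unname(area),
             percent = if (tot > 0) unname(100 * area / tot) else 0,
             stringsAsFactors = FALSE)
}

#' Share of a land-use class lying inside the stable suitable area
#'
#' `(class area inside stable) / (class area everywhere) * 100`.
#'
#' @param stable binary `grid_layer`.
#' @param lu a `land_use_layer`.
#' @param class_name class to summarize (must occur somewhere).
#' @param cell_areas co-registered area layer (km2).
#' @return percent.
#' @export
class_share_inside <- function(stable, lu, class_name, cell_areas) {
  assert_coregistered(list(stable, lu$grid, cell_areas))
  code <- lu$codes[[class_name]]
  if (is.null(code)) stop("unknown land-use class: ", class_name)
  is_cls <- is.finite(lu$grid$values) & lu$grid$values == code
  tot <- sum(cell_areas$values[is_cls])
  if (tot == 0) stop("class '", class_name, "' absent from the land-use layer")
  inside <- is_cls & is.finite(stable$values) & stable$values == 1
  100 * sum(cell_areas$values[inside]) / tot
}

#' Suitable area by land-use class across periods and scenarios
#'
#' Binarizes each suitability layer at `theta` and tabulates the suitable
#' area within each land-use class. `lu` may be a single `land_use_layer`
#' (reused for all periods) or a named list parallel to `suitability`.
#'
#' @param suitability named list of continuous suitability `grid_layer`s
#'   (names identify the period/scenario).
#' @param lu a `land_use_layer` or named list of them.
#' @param cell_areas co-registered area layer (km2).
#' @param theta suitability threshold (default 0.4).
#' @return data.frame with `period`, `class`, `area_km2`.
#' @export
suitable_area_by_landuse <- function(suitability, lu, cell_areas, theta = 0.4) {
  per_lu <- function(nm) if (inherits(lu, "land_use_layer")) lu else lu[[nm]]
  out <- lapply(names(suitability), function(nm) {
    l <- per_lu(nm)
    b <- binarize(suitability[[nm]], theta)
    comp <- landuse_composition(b, l, cell_areas)
    data.frame(period = nm, class = comp$class, area_km2 = comp$area_km2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a land-use code table as plain text
#' @param lu a `land_use_layer`.
#' @param path output path.
#' @export
write_code_table <- function(lu, path) {
  utils::write.table(data.frame(class = names(lu$codes), code = lu$codes),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
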