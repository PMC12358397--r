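#' Geographic raster layer
#'
#' A `grid_layer` is a single co-registered geographic raster on a regular
#' lon/lat grid with square cells. Row 1 of `values` is the **northernmost**
#' row; cells are corner-registered at the lower-left corner (`xll`, `yll`).
#' Missing cells are stored as `NA` internally and written out as
#' `nodata_value`.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll longitude/latitude of the lower-left corner, in degrees.
#' @param cellsize cell edge length in degrees (square cells).
#' @param nodata_value sentinel written to file for `NA` cells.
#' @param kind one of `"continuous"`, `"binary"`, `"class4"`, `"categorical"`.
#'
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(values, xll, yll, cellsize, nodata_value = -9999,
                       kind = c("continuous", "binary", "class4", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  nrows <- nrow(values); ncols <- ncol(values)
  stopifnot(nrows >= 1, ncols >= 1, is.finite(xll), is.finite(yll), cellsize > 0)
  if (xll < -180 || xll + ncols * cellsize > 360)
    stop("grid extent outside [-180, 360] degrees longitude")
  if (yll < -90 || yll + nrows * cellsize > 90 + 1e-9)
    stop("grid extent outside [-90, 90] degrees latitude")
  fin <- values[is.finite(values)]
  if (kind == "binary" && !all(fin %in% c(0, 1)))
    stop("binary layer contains values outside {0, 1}")
  if (kind == "class4" && !all(fin %in% 0:3))
    stop("class4 layer contains values outside {0, 1, 2, 3}")
  structure(list(values = values, nrows = nrows, ncols = ncols,
                 xll = xll, yll = yll, cellsize = cellsize,
                 nodata_value = nodata_value, kind = kind),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  cat(sprintf("<grid_layer %s> %d x %d cells of %g deg, origin (%g, %g)\n",
              x$kind, x$nrows, x$ncols, x$cellsize, x$xll, x$yll))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  %d valid cells, range [%g, %g]\n", length(v), min(v), max(v)))
  else cat("  no valid cells\n")
  invisible(x)
}

#' @export
dim.grid_layer <- function(x) c(x$nrows, x$ncols)

#' @export
as.matrix.grid_layer <- function(x, ...) x$values

#' @export
plot.grid_layer <- function(x, main = "", ...) {
  # image() draws row 1 at the bottom; flip so north is up
  z <- t(x$values[x$nrows:1, , drop = FALSE])
  lon <- x$xll + (seq_len(x$ncols) - 0.5) * x$cellsize
  lat <- x$yll + (seq_len(x$nrows) - 0.5) * x$cellsize
  graphics::image(lon, lat, z, main = main, xlab = "longitude", ylab = "latitude",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Cell-center coordinates of a grid layer
#'
#' @param layer a `grid_layer`.
#' @return list with `lon` (length ncols) and `lat` (length nrows, row 1 =
#'   northernmost row, so `lat` is decreasing).
#' @export
cell_centers <- function(layer) {
  list(lon = layer$xll + (seq_len(layer$ncols) - 0.5) * layer$cellsize,
       lat = layer$yll + (layer$nrows - seq_len(layer$nrows) + 0.5) * layer$cellsize)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard `.asc` header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by row-major
#' values north to south. Nodata cells become `NA`.
#'
#' @param path file path.
#' @param kind layer kind, see [grid_layer()].
#' @return A `grid_layer`.
#' @export
read_ascii_grid <- function(path, kind = "continuous") {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  hdr <- list(); i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-+0-9.eE]+\\s*$", lines[[i]])) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(val)) stop(sprintf("line %d: non-numeric header value '%s'", i, tok[2]))
    hdr[[tolower(tok[1])]] <- val
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("malformed header, missing: ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nrows <- as.integer(hdr$nrows); ncols <- as.integer(hdr$ncols)
  vals <- matrix(NA_real_, nrows, ncols)
  r <- 0
  for (k in seq(i, length.out = length(lines) - i + 1)) {
    ln <- trimws(lines[[k]])
    if (!nzchar(ln)) next
    r <- r + 1
    if (r > nrows) stop(sprintf("line %d: more data rows than nrows=%d", k, nrows))
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != ncols)
      stop(sprintf("line %d: %d values where ncols=%d expected", k, length(tok), ncols))
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric cell value", k))
    vals[r, ] <- v
  }
  if (r != nrows) stop(sprintf("expected %d data rows, found %d", nrows, r))
  vals[vals == nodata] <- NA_real_
  grid_layer(vals, xll = hdr$xllcorner, yll = hdr$yllcorner,
             cellsize = hdr$cellsize, nodata_value = nodata, kind = kind)
}

#' Write an ESRI ASCII grid
#'
#' Round-trips through [read_ascii_grid()]: values, the nodata mask and the
#' header are preserved. Header floats are written with 12 significant
#' digits.
#'
#' @param layer a `grid_layer`.
#' @param path output path.
#' @export
write_ascii_grid <- function(layer, path) {
  stopifnot(inherits(layer, "grid_layer"))
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  writeLines(c(paste("ncols", layer$ncols),
               paste("nrows", layer$nrows),
               paste("xllcorner", fmt(layer$xll)),
               paste("yllcorner", fmt(layer$yll)),
               paste("cellsize", fmt(layer$cellsize)),
               paste("NODATA_value", fmt(layer$nodata_value))), con)
  v <- layer$values
  v[!is.finite(v)] <- layer$nodata_value
  writeLines(apply(v, 1, function(row) paste(fmt(row), collapse = " ")), con)
  invisible(NULL)
}

#' Check that layers share one grid
#'
#' Two layers are co-registered when `nrows`, `ncols`, `xll`, `yll` and
#' `cellsize` agree within 1e-9 degrees. Errors name the offending field and
#' layer index.
#'
#' @param layers list of `grid_layer` objects.
#' @export
assert_coregistered <- function(layers) {
  stopifnot(length(layers) >= 1)
  ref <- layers[[1]]
  for (idx in seq_along(layers)[-1]) {
    g <- layers[[idx]]
    for (f in c("nrows", "ncols", "xll", "yll", "cellsize")) {
      if (abs(g[[f]] - ref[[f]]) > 1e-9)
        stop(sprintf("layer %d not co-registered: %s is %.10g, expected %.10g",
                     idx, f, g[[f]], ref[[f]]))
    }
  }
  invisible(NULL)
}

#' Spherical cell-area layer
#'
#' Area of each cell in km2 on a sphere: the latitude-band slice
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))`. Independent of
#' longitude, so all cells in one row have equal area. The default radius is
#' the WGS84 authalic radius.
#'
#' @param template a `grid_layer` defining the grid.
#' @param radius_km sphere radius in km.
#' @return continuous `grid_layer` of per-cell areas (km2).
#' @export
cell_area_layer <- function(template, radius_km = 6371.0072) {
  stopifnot(inherits(template, "grid_layer"))
  cs <- template$cellsize
  top <- template$yll + (template$nrows - seq_len(template$nrows) + 1) * cs
  bot <- top - cs
  if (any(top > 90 + 1e-9) || any(bot < -90 - 1e-9))
    stop("cell spans beyond +-90 degrees latitude")
  band <- radius_km^2 * (cs * pi / 180) *
    (sin(pmin(top, 90) * pi / 180) - sin(pmax(bot, -90) * pi / 180))
  grid_layer(matrix(band, template$nrows, template$ncols),
             xll = template$xll, yll = template$yll, cellsize = cs,
             nodata_value = template$nodata_value, kind = "continuous")
}

#' Locate points on a grid
#'
#' Maps lon/lat points to 1-based (row, col) indices using half-open cell
#' intervals `[west, east) x (south, north]`, so each point falls in exactly
#' one cell. Points outside the extent get `NA`.
#'
#' @param layer a `grid_layer`.
#' @param lon,lat coordinate vectors (degrees).
#' @return data.frame with columns `row`, `col` (`NA` when outside).
#' @export
locate_cells <- function(layer, lon, lat) {
  col <- floor((lon - layer$xll) / layer$cellsize) + 1
  band <- ceiling((lat - layer$yll) / layer$cellsize)  # 1 = southernmost band
  row <- layer$nrows - band + 1
  bad <- col < 1 | col > layer$ncols | band < 1 | band > layer$nrows |
    !is.finite(lon) | !is.finite(lat)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract layer values at points
#'
#' @param layers named list of co-registered `grid_layer`s.
#' @param lon,lat coordinate vectors.
#' @return data.frame, one column per layer; `NA` for nodata or
#'   out-of-extent points.
#' @export
extract_values <- function(layers, lon, lat) {
  assert_coregistered(layers)
  cells <- locate_cells(layers[[1]], lon, lat)
  idx <- cbind(cells$row, cells$col)
  out <- lapply(layers, function(g) {
    v <- rep(NA_real_, nrow(idx))
    ok <- !is.na(cells$row)
    v[ok] <- g$values[idx[ok, , drop = FALSE]]
    v
  })
  as.data.frame(out, optional = TRUE)
}
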