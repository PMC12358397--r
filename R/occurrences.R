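#' Occurrence records
#'
#' An `occurrences` object is a data.frame with columns `species`, `lon`,
#' `lat` and `source`, one presence record per row.
#'
#' @param species character vector (recycled).
#' @param lon,lat coordinates in degrees; lon in [-180, 360), lat in [-90, 90].
#' @param source free-text provenance (recycled).
#' @return An object of class `occurrences` (a data.frame).
#' @export
occurrences <- function(species, lon, lat, source = "") {
  stopifnot(length(lon) == length(lat))
  if (length(lon) && (any(lon < -180 | lon >= 360) || any(abs(lat) > 90)))
    stop("coordinates outside lon [-180, 360) / lat [-90, 90]")
  out <- data.frame(species = rep_len(as.character(species), length(lon)),
                    lon = as.numeric(lon), lat = as.numeric(lat),
                    source = rep_len(as.character(source), length(lon)),
                    stringsAsFactors = FALSE)
  class(out) <- c("occurrences", "data.frame")
  out
}

#' Read occurrence records from delimited text
#'
#' Expects a header with columns `species`, `longitude`, `latitude`
#' (case-insensitive; `lon`/`lat` also accepted). Comma and tab delimiters
#' are auto-detected. Rows whose coordinates do not parse are dropped with a
#' message giving the count.
#'
#' @param path file path.
#' @return An `occurrences` object.
#' @export
read_occurrences <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  nm <- tolower(names(df))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (!length(hit)) stop("missing required column: ", cands[1])
    hit[1]
  }
  sp <- df[[pick("species")]]
  lon <- suppressWarnings(as.numeric(df[[pick(c("longitude", "lon"))]]))
  lat <- suppressWarnings(as.numeric(df[[pick(c("latitude", "lat"))]]))
  src <- if ("source" %in% nm) df[[which(nm == "source")[1]]] else ""
  bad <- is.na(lon) | is.na(lat)
  if (any(bad))
    message(sum(bad), " row(s) with unparseable coordinates dropped")
  occurrences(sp[!bad], lon[!bad], lat[!bad],
              if (length(src) > 1) src[!bad] else src)
}

#' Write occurrences as CSV
#' @param occ an `occurrences` object.
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(data.frame(species = occ$species, longitude = occ$lon,
                              latitude = occ$lat, source = occ$source),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Remove exact coordinate duplicates
#'
#' Collapses records with identical (lon, lat) to the first occurrence,
#' preserving input order.
#'
#' @param occ an `occurrences` object.
#' @return Deduplicated `occurrences`.
#' @export
deduplicate <- function(occ) {
  keep <- !duplicated(paste(format(occ$lon, digits = 15),
                            format(occ$lat, digits = 15)))
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrences", "data.frame")
  out
}

#' Keep records inside a binary region mask
#'
#' Records are kept when their containing cell (half-open assignment, see
#' [locate_cells()]) has mask value 1; records outside the grid extent or in
#' nodata cells are removed.
#'
#' @param occ an `occurrences` object.
#' @param mask a binary `grid_layer`.
#' @return Filtered `occurrences`.
#' @export
filter_to_region <- function(occ, mask) {
  stopifnot(inherits(mask, "grid_layer"), mask$kind == "binary")
  cells <- locate_cells(mask, occ$lon, occ$lat)
  ok <- !is.na(cells$row)
  ok[ok] <- !is.na(mask$values[cbind(cells$row[ok], cells$col[ok])]) &
    mask$values[cbind(cells$row[ok], cells$col[ok])] == 1
  out <- occ[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrences", "data.frame")
  out
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Within each cell of the template grid, the first record in input order is
#' retained; records outside the extent are dropped. Idempotent.
#'
#' @param occ an `occurrences` object.
#' @param template a `grid_layer` defining the thinning grid.
#' @return Thinned `occurrences`.
#' @export
thin_to_grid <- function(occ, template) {
  stopifnot(inherits(template, "grid_layer"))
  cells <- locate_cells(template, occ$lon, occ$lat)
  inside <- !is.na(cells$row)
  lin <- (cells$row - 1L) * template$ncols + cells$col
  keep <- inside & !duplicated(lin)
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("occurrences", "data.frame")
  out
}
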