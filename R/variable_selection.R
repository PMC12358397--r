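#' Pairwise correlation matrix of predictor layers
#'
#' Product-moment correlation computed over cells valid in **all** layers.
#' A zero-variance layer yields `NA` entries and a warning (never a silent
#' zero).
#'
#' @param layers named list of >= 2 co-registered `grid_layer`s with >= 3
#'   jointly valid cells.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(layers) {
  assert_coregistered(layers)
  stopifnot(length(layers) >= 2)
  ok <- Reduce(`&`, lapply(layers, function(l) is.finite(l$values)))
  if (sum(ok) < 3) stop("fewer than 3 jointly valid cells")
  X <- vapply(layers, function(l) l$values[ok], numeric(sum(ok)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance layer(s): ",
            paste(names(layers)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  r
}

#' Contribution-aware collinearity filter
#'
#' First drops layers whose contribution is not positive. Then, among the
#' remainder, repeatedly finds the pair with the largest `|r| >=
#' r_threshold` and drops the member with the lower contribution, until no
#' pair exceeds the threshold. Ties in contribution are broken by input
#' order (the later layer is dropped). Deterministic given the
#' contributions.
#'
#' @param layers named list of co-registered `grid_layer`s.
#' @param contributions named percentages (one per layer) from a
#'   preliminary fit, e.g. [permutation_importance()].
#' @param r_threshold absolute-correlation cutoff (default 0.8).
#' @return A `selection_report`: `kept` (names), `dropped` (data.frame
#'   name, partner, r, reason) and `correlation` (full matrix).
#' @export
select_variables <- function(layers, contributions, r_threshold = 0.8) {
  miss <- setdiff(names(layers), names(contributions))
  if (length(miss)) stop("missing contribution for: ", paste(miss, collapse = ", "))
  r <- correlation_matrix(layers)
  nms <- names(layers)
  dropped <- data.frame(name = character(), partner = character(),
                        r = double(), reason = character(),
                        stringsAsFactors = FALSE)
  keep <- nms
  zero <- keep[contributions[keep] <= 0]
  for (z in zero)
    dropped <- rbind(dropped, data.frame(name = z, partner = NA_character_,
                                         r = NA_real_,
                                         reason = "contribution <= 0"))
  keep <- setdiff(keep, zero)
  repeat {
    if (length(keep) < 2) break
    sub <- abs(r[keep, keep, drop = FALSE])
    diag(sub) <- 0
    mx <- max(sub, na.rm = TRUE)
    if (!is.finite(mx) || mx < r_threshold) break
    ij <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    # lower contribution loses; tie -> the later layer in input order
    loser <- if (contributions[a] < contributions[b]) a
             else if (contributions[b] < contributions[a]) b
             else keep[max(ij)]
    winner <- setdiff(c(a, b), loser)
    dropped <- rbind(dropped, data.frame(name = loser, partner = winner,
                                         r = r[loser, winner],
                                         reason = sprintf("|r| >= %g", r_threshold)))
    keep <- setdiff(keep, loser)
  }
  structure(list(kept = keep, dropped = dropped, correlation = r,
                 r_threshold = r_threshold),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d kept, %d dropped (|r| >= %g rule)\n",
              length(x$kept), nrow(x$dropped), x$r_threshold))
  cat("kept:", paste(x$kept, collapse = ", "), "\n")
  if (nrow(x$dropped)) print(x$dropped, row.names = FALSE)
  invisible(x)
}

#' Write a selection report (and its correlation matrix) as delimited text
#' @param report a `selection_report`.
#' @param path output path for the drop report; the matrix goes to
#'   `<path>.cor.tsv`.
#' @export
write_selection_report <- function(report, path) {
  utils::write.table(
    rbind(data.frame(name = report$kept, partner = NA, r = NA, reason = "kept"),
          report$dropped),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$correlation, paste0(path, ".cor.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(NULL)
}
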