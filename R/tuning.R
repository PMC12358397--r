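#' Sample-size-corrected AIC for a maxent fit
#'
#' The raw Gibbs density is standardized to sum to 1 over **all** valid
#' study cells; the log likelihood is the sum of log standardized densities
#' at the presence points; `k` is the number of non-zero coefficients.
#' `AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)` with `n` presences. Returns `NA`
#' (undefined) when `k = 0` or `k >= n - 1`. Presences falling in nodata
#' cells are excluded with a warning.
#'
#' @param model a `maxent` fit.
#' @param occ presence `occurrences`.
#' @param layers named list of predictor `grid_layer`s (the study grid).
#' @return AICc, or `NA_real_` when undefined.
#' @export
aicc <- function(model, occ, layers) {
  raw <- predict(model, layers, type = "raw")
  tot <- sum(raw$values, na.rm = TRUE)
  cells <- locate_cells(raw, occ$lon, occ$lat)
  pr <- rep(NA_real_, nrow(cells))
  ok <- !is.na(cells$row)
  pr[ok] <- raw$values[cbind(cells$row[ok], cells$col[ok])]
  if (anyNA(pr)) {
    warning(sum(is.na(pr)), " presence(s) in nodata cells excluded from AICc")
    pr <- pr[!is.na(pr)]
  }
  n <- length(pr)
  k <- model$k_nonzero
  if (k == 0 || k >= n - 1) return(NA_real_)
  lnL <- sum(log(pr / tot))
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Tune feature combination and regularization multiplier by AICc
#'
#' Fits every (FC, RM) combination on a shared background sample and a
#' shared train/test split, computes AICc over the study grid and test AUC,
#' and selects the row with `delta.AICc = 0`. Ties are broken by smaller
#' `k`, then larger `rm`, then FC order as listed.
#'
#' @param occ presence `occurrences`.
#' @param layers named list of predictor `grid_layer`s.
#' @param fcs character vector of feature-class labels
#'   (default the six-combination grid `l, lq, lqh, h, lqhp, lqhpt`).
#' @param rms regularization multipliers (default 0.5 to 4 by 0.5).
#' @param n_background background sample size.
#' @param test_fraction held-out fraction for the AUC column.
#' @param seed integer seed shared by all combinations.
#' @param hinge_knots,threshold_knots knot counts passed to [feature_spec()].
#' @return A `maxent_tuning` object: `results` (data.frame with fc, rm, k,
#'   aicc, delta_aicc, test_auc), `selected` (list fc, rm) and the selected
#'   refitted `model` (fit on all presences).
#' @export
tune_maxent <- function(occ, layers,
                        fcs = c("l", "lq", "lqh", "h", "lqhp", "lqhpt"),
                        rms = seq(0.5, 4, by = 0.5),
                        n_background = 10000, test_fraction = 0.25,
                        seed = NULL, hinge_knots = 50, threshold_knots = 50) {
  assert_coregistered(layers)
  mask <- valid_mask(layers)
  bg <- sample_background(mask, n_background, seed = seed)
  bg_data <- extract_values(layers, bg$lon, bg$lat)
  pres_data <- extract_values(layers, occ$lon, occ$lat)
  keep <- stats::complete.cases(pres_data)
  occ <- occ[keep, , drop = FALSE]; pres_data <- pres_data[keep, , drop = FALSE]
  sp <- split_presences(occ, test_fraction, seed = seed)
  tr_data <- extract_values(layers, sp$train$lon, sp$train$lat)
  te_data <- extract_values(layers, sp$test$lon, sp$test$lat)

  rows <- expand.grid(fc = fcs, rm = rms, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- rows[order(match(rows$fc, fcs), rows$rm), ]
  res <- lapply(seq_len(nrow(rows)), function(i) {
    spec <- feature_spec(rows$fc[i], hinge_knots, threshold_knots)
    fit <- suppressWarnings(maxent(pres_data, bg_data, spec, rm = rows$rm[i]))
    a <- suppressWarnings(aicc(fit, occ, layers))
    te_fit <- suppressWarnings(maxent(tr_data, bg_data, spec, rm = rows$rm[i]))
    auc <- auc_mw(predict(te_fit, te_data, type = "raw"),
                  predict(te_fit, bg_data, type = "raw"))
    data.frame(fc = toupper(rows$fc[i]), rm = rows$rm[i], k = fit$k_nonzero,
               aicc = a, test_auc = auc, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (all(is.na(res$aicc)))
    stop("AICc undefined for every combination; more presences are needed")
  res$delta_aicc <- res$aicc - min(res$aicc, na.rm = TRUE)
  cand <- which(!is.na(res$delta_aicc) & res$delta_aicc == 0)
  cand <- cand[order(res$k[cand], -res$rm[cand], cand)]
  sel <- cand[1]
  spec <- feature_spec(res$fc[sel], hinge_knots, threshold_knots)
  model <- suppressWarnings(maxent(pres_data, bg_data, spec, rm = res$rm[sel]))
  structure(list(results = res[, c("fc", "rm", "k", "aicc", "delta_aicc",
                                   "test_auc")],
                 selected = list(fc = res$fc[sel], rm = res$rm[sel]),
                 model = model, seed = seed),
            class = "maxent_tuning")
}

#' @export
print.maxent_tuning <- function(x, ...) {
  cat(sprintf("<maxent_tuning> %d combinations; selected FC = %s, RM = %g\n",
              nrow(x$results), x$selected$fc, x$selected$rm))
  print(utils::head(x$results[order(x$results$delta_aicc), ], 5),
        row.names = FALSE)
  invisible(x)
}

#' Write a tuning table as delimited text
#' @param tuning a `maxent_tuning` object.
#' @param path output path.
#' @export
write_tuning_table <- function(tuning, path) {
  utils::write.table(tuning$results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}

#' Joint validity mask of a layer stack
#'
#' Binary layer: 1 where every input layer is finite, `NA` elsewhere.
#'
#' @param layers named list of co-registered `grid_layer`s.
#' @return binary `grid_layer`.
#' @export
valid_mask <- function(layers) {
  assert_coregistered(layers)
  g <- layers[[1]]
  ok <- Reduce(`&`, lapply(layers, function(l) is.finite(l$values)))
  m <- matrix(NA_real_, g$nrows, g$ncols)
  m[ok] <- 1
  grid_layer(m, g$xll, g$yll, g$cellsize, g$nodata_value, "binary")
}
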