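#' Random train/test split of presence records
#'
#' Partitions presences into training and test sets; the test set holds
#' `floor(n * test_fraction)` records. Reproducible under `seed`; the split
#' is disjoint and exhaustive.
#'
#' @param occ an `occurrences` object (>= 4 records).
#' @param test_fraction held-out fraction (default 0.25).
#' @param seed integer seed (RNG state restored).
#' @return list with `train` and `test` `occurrences`.
#' @export
split_presences <- function(occ, test_fraction = 0.25, seed = NULL) {
  n <- nrow(occ)
  if (n < 4) stop("need at least 4 presences to split")
  n_test <- floor(n * test_fraction)
  idx <- with_seed(seed, sample.int(n, n_test))
  test <- occ[sort(idx), , drop = FALSE]
  train <- occ[setdiff(seq_len(n), idx), , drop = FALSE]
  rownames(test) <- rownames(train) <- NULL
  class(test) <- class(train) <- c("occurrences", "data.frame")
  list(train = train, test = test)
}

#' Presence-background AUC (rank-sum)
#'
#' Mann-Whitney AUC: the fraction of (presence, background) score pairs in
#' which the presence scores higher, ties counted one half. Invariant to
#' monotone transforms of the scores; 0.5 when all scores are identical.
#'
#' @param presence_scores,background_scores numeric vectors (non-empty).
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(presence_scores, background_scores) {
  stopifnot(length(presence_scores) > 0, length(background_scores) > 0)
  np <- length(presence_scores); nn <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Replicate fits with train/test evaluation and a mean suitability layer
#'
#' Runs `n_replicates` independent splits and fits (each replicate draws its
#' own split and background seeds from the master seed), records train and
#' test AUC, and returns the cell-wise mean of the logistic predictions as
#' the working suitability layer.
#'
#' @param occ presence `occurrences`.
#' @param layers named list of predictor `grid_layer`s.
#' @param spec a [feature_spec()].
#' @param rm regularization multiplier.
#' @param n_replicates number of replicates (default 10).
#' @param n_background background sample size per replicate.
#' @param test_fraction held-out fraction.
#' @param seed master integer seed.
#' @return list: `report` (an `evaluation_report`: `replicate_aucs`
#'   data.frame, `mean_test_auc`, `sd_test_auc`), `mean_layer` (continuous
#'   `grid_layer`), `models` (list of `maxent` fits).
#' @export
replicate_fit <- function(occ, layers, spec = feature_spec("lq"), rm = 1,
                          n_replicates = 10, n_background = 10000,
                          test_fraction = 0.25, seed = 1) {
  assert_coregistered(layers)
  mask <- valid_mask(layers)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_replicates))
  acc <- NULL; models <- list()
  aucs <- data.frame(replicate = integer(), train_auc = double(),
                     test_auc = double())
  for (r in seq_len(n_replicates)) {
    s <- sub_seeds[r]
    bg <- sample_background(mask, n_background, seed = s)
    bg_data <- extract_values(layers, bg$lon, bg$lat)
    sp <- split_presences(occ, test_fraction, seed = s + 1L)
    tr <- extract_values(layers, sp$train$lon, sp$train$lat)
    te <- extract_values(layers, sp$test$lon, sp$test$lat)
    fit <- suppressWarnings(maxent(tr, bg_data, spec, rm = rm))
    bg_sc <- predict(fit, bg_data, type = "raw")
    aucs <- rbind(aucs, data.frame(
      replicate = r,
      train_auc = auc_mw(predict(fit, tr, type = "raw"), bg_sc),
      test_auc = if (nrow(te)) auc_mw(predict(fit, te, type = "raw"), bg_sc)
                 else NA_real_))
    pl <- predict(fit, layers, type = "logistic")
    acc <- if (is.null(acc)) pl$values else acc + pl$values
    models[[r]] <- fit
  }
  g <- layers[[1]]
  mean_layer <- grid_layer(acc / n_replicates, g$xll, g$yll, g$cellsize,
                           g$nodata_value, "continuous")
  report <- structure(list(replicate_aucs = aucs,
                           mean_test_auc = mean(aucs$test_auc, na.rm = TRUE),
                           sd_test_auc = stats::sd(aucs$test_auc)),
                      class = "evaluation_report")
  list(report = report, mean_layer = mean_layer, models = models)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d replicates; test AUC %.3f +/- %.3f (sd)\n",
              nrow(x$replicate_aucs), x$mean_test_auc, x$sd_test_auc))
  invisible(x)
}

#' Permutation importance ("percent contribution")
#'
#' For each variable, the mean drop in presence-background AUC when that
#' variable's values are permuted across the evaluation cells (presences and
#' background jointly), floored at zero and normalized to sum to 100. When
#' no permutation lowers the AUC the shares are returned uniform with a
#' warning.
#'
#' @param model a `maxent` fit.
#' @param presence,background data.frames of raw predictor values.
#' @param seed integer seed.
#' @param n_perm permutations per variable.
#' @return named numeric vector of percentages summing to 100.
#' @export
permutation_importance <- function(model, presence, background, seed = NULL,
                                   n_perm = 10) {
  presence <- as.data.frame(presence); background <- as.data.frame(background)
  base <- auc_mw(predict(model, presence, type = "raw"),
                 predict(model, background, type = "raw"))
  np <- nrow(presence)
  all_data <- rbind(presence, background)
  vars <- model$variable_names
  drops <- with_seed(seed, {
    vapply(vars, function(v) {
      d <- vapply(seq_len(n_perm), function(i) {
        perm <- all_data
        perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
        sc <- predict(model, perm, type = "raw")
        base - auc_mw(sc[seq_len(np)], sc[-seq_len(np)])
      }, 0)
      mean(d)
    }, 0)
  })
  drops <- pmax(drops, 0)
  if (sum(drops) <= 0) {
    warning("no permutation reduced AUC; returning uniform contributions")
    return(stats::setNames(rep(100 / length(vars), length(vars)), vars))
  }
  100 * drops / sum(drops)
}

#' Jackknife training gains per variable
#'
#' Regularized training gain (`mean_presence(lambda . f) - log Z +
#' log n_background`; 0 for the null model) of the model fit with only each
#' variable, and with all variables but that one, alongside the full-model
#' gain.
#'
#' @param occ presence `occurrences`.
#' @param layers named list of predictor `grid_layer`s (>= 2).
#' @param spec a [feature_spec()].
#' @param rm regularization multiplier.
#' @param n_background background sample size.
#' @param seed integer seed (shared background).
#' @return list: `gains` data.frame (variable, gain_alone, gain_without),
#'   `full_gain`.
#' @export
jackknife_gains <- function(occ, layers, spec = feature_spec("lq"), rm = 1,
                            n_background = 10000, seed = NULL) {
  stopifnot(length(layers) >= 2)
  mask <- valid_mask(layers)
  bg <- sample_background(mask, n_background, seed = seed)
  bg_data <- extract_values(layers, bg$lon, bg$lat)
  pres <- extract_values(layers, occ$lon, occ$lat)
  pres <- pres[stats::complete.cases(pres), , drop = FALSE]
  fit_gain <- function(cols) {
    f <- suppressWarnings(maxent(pres[, cols, drop = FALSE],
                                 bg_data[, cols, drop = FALSE], spec, rm = rm))
    f$gain
  }
  vars <- names(layers)
  gains <- data.frame(
    variable = vars,
    gain_alone = vapply(vars, function(v) fit_gain(v), 0),
    gain_without = vapply(vars, function(v) fit_gain(setdiff(vars, v)), 0),
    stringsAsFactors = FALSE)
  list(gains = gains, full_gain = fit_gain(vars))
}

#' Write an evaluation summary as key-value text
#' @param report an `evaluation_report`.
#' @param contributions optional named percentage vector.
#' @param path output path.
#' @export
write_evaluation_report <- function(report, path, contributions = NULL) {
  lines <- c(sprintf("mean_test_auc\t%.3f", report$mean_test_auc),
             sprintf("sd_test_auc\t%.3f", report$sd_test_auc),
             sprintf("test_auc_formatted\t%.3f ± %.3f (sd)",
                     report$mean_test_auc, report$sd_test_auc))
  if (!is.null(contributions))
    lines <- c(lines, sprintf("contribution_%s\t%.2f",
                              names(contributions), contributions))
  writeLines(lines, path)
  invisible(NULL)
}
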