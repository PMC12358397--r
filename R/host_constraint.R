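#' Append host suitability to a predictor stack
#'
#' For the Parasitic Constraint Scenario the host's suitability layer
#' enters the parasite model as one more continuous predictor, named
#' `P_HA`. Cells that are nodata in the host layer become nodata in every
#' layer of the returned stack so both scenarios see a consistent domain.
#'
#' @param env_layers named list of co-registered predictor `grid_layer`s.
#' @param host_suitability continuous `grid_layer` in [0, 1].
#' @return named list of `grid_layer`s: the predictors plus `P_HA`.
#' @export
build_pcs_predictors <- function(env_layers, host_suitability) {
  assert_coregistered(c(env_layers, list(host_suitability)))
  bad <- !is.finite(host_suitability$values)
  out <- lapply(env_layers, function(g) {
    v <- g$values; v[bad] <- NA_real_
    grid_layer(v, g$xll, g$yll, g$cellsize, g$nodata_value, g$kind)
  })
  out$P_HA <- host_suitability
  out
}

#' Conditional probability transfer (obligate-parasitism mask)
#'
#' Implements host dependency as a hard constraint: wherever host
#' suitability `P_HA` falls below the effective-parasitism threshold
#' `theta`, parasite suitability `P_CD` is forced to zero; where
#' `P_HA >= theta` the parasite's own prediction stands. Idempotent;
#' nodata in either layer propagates.
#'
#' @param p_cd parasite suitability `grid_layer` in [0, 1].
#' @param p_ha host suitability `grid_layer` in [0, 1].
#' @param theta parasitism threshold in (0, 1), default 0.4 (the
#'   medium-or-high suitability cut).
#' @return continuous `grid_layer`.
#' @export
conditional_probability_transfer <- function(p_cd, p_ha, theta = 0.4) {
  if (!(theta > 0 && theta < 1)) stop("theta must lie in (0, 1)")
  assert_coregistered(list(p_cd, p_ha))
  v <- ifelse(p_ha$values >= theta, p_cd$values, 0)
  v[!is.finite(p_cd$values) | !is.finite(p_ha$values)] <- NA_real_
  grid_layer(v, p_cd$xll, p_cd$yll, p_cd$cellsize, p_cd$nodata_value,
             "continuous")
}

#' Area difference rate between scenarios
#'
#' `((area_pcs - area_nhs) / area_nhs) * 100`, in percent. Vectorized; a
#' zero reference area yields `NA` with a warning.
#'
#' @param area_pcs area under the Parasitic Constraint Scenario.
#' @param area_nhs area under the Natural Habitat Scenario (same units).
#' @return percent difference (negative = loss under the constraint).
#' @export
area_difference_rate <- function(area_pcs, area_nhs) {
  out <- (area_pcs - area_nhs) / area_nhs * 100
  if (any(area_nhs == 0)) {
    warning("reference (NHS) area is zero; rate undefined")
    out[area_nhs == 0] <- NA_real_
  }
  out
}

#' Run the Natural Habitat and Parasitic Constraint scenarios
#'
#' NHS: the parasite is modelled from the environmental predictors only.
#' PCS: the host's mean replicate suitability layer is added as the `P_HA`
#' predictor, the parasite refit, and the conditional probability transfer
#' applied to the mean replicate prediction. Both scenarios are classified,
#' their per-class areas compared via the area difference rate, and the
#' area-weighted centroids of the binary suitable regions located.
#'
#' @param occ parasite presence `occurrences`.
#' @param env_layers named list of predictor `grid_layer`s.
#' @param host either a fitted host suitability `grid_layer` in [0, 1], or
#'   host `occurrences` (the host model is then fit first with
#'   `host_spec`/`host_rm`).
#' @param spec,rm parasite feature spec and regularization multiplier
#'   (used for both scenarios).
#' @param host_spec,host_rm host model settings (defaults: LQHPT, RM 2.5).
#' @param theta parasitism threshold (default 0.4).
#' @param breaks classification breaks (default 0.2 / 0.4 / 0.6).
#' @param n_replicates,n_background,test_fraction see [replicate_fit()].
#' @param seed master integer seed.
#' @return A `scenario_comparison`: `class_areas` (data.frame of NHS/PCS
#'   areas and difference rates per class plus the binary suitable total),
#'   `centroids`, `centroid_shift_km`, `layers` (mean and constrained
#'   suitability), `reports` (host/NHS/PCS evaluation reports), `theta`.
#' @export
run_two_scenarios <- function(occ, env_layers, host,
                              spec = feature_spec("lq"), rm = 1,
                              host_spec = feature_spec("lqhpt"), host_rm = 2.5,
                              theta = 0.4, breaks = c(0.2, 0.4, 0.6),
                              n_replicates = 10, n_background = 10000,
                              test_fraction = 0.25, seed = 1) {
  if (!(theta > 0 && theta < 1)) stop("theta must lie in (0, 1)")
  assert_coregistered(env_layers)
  host_report <- NULL; host_models <- NULL
  if (inherits(host, "grid_layer")) {
    p_ha <- host
  } else {
    host_fit <- replicate_fit(host, env_layers, host_spec, host_rm,
                              n_replicates, n_background, test_fraction,
                              seed = seed + 1L)
    p_ha <- host_fit$mean_layer
    host_report <- host_fit$report
    host_models <- host_fit$models
  }
  assert_coregistered(c(env_layers, list(p_ha)))

  nhs_fit <- replicate_fit(occ, env_layers, spec, rm, n_replicates,
                           n_background, test_fraction, seed = seed + 2L)
  pcs_layers <- build_pcs_predictors(env_layers, p_ha)
  pcs_fit <- replicate_fit(occ, pcs_layers, spec, rm, n_replicates,
                           n_background, test_fraction, seed = seed + 3L)
  p_nhs <- nhs_fit$mean_layer
  p_pcs <- conditional_probability_transfer(pcs_fit$mean_layer, p_ha, theta)

  areas_km2 <- cell_area_layer(p_nhs)
  cls_nhs <- class_areas(classify_suitability(p_nhs, breaks), areas_km2)
  cls_pcs <- class_areas(classify_suitability(p_pcs, breaks), areas_km2)
  tab <- merge(data.frame(class = 0:3, label = class4_labels()),
               cls_nhs[, c("class", "area_km2")], by = "class", all.x = TRUE)
  names(tab)[3] <- "nhs_km2"
  tab <- merge(tab, cls_pcs[, c("class", "area_km2")], by = "class", all.x = TRUE)
  names(tab)[4] <- "pcs_km2"
  tab[is.na(tab)] <- 0

  bin_nhs <- binarize(p_nhs, theta); bin_pcs <- binarize(p_pcs, theta)
  suit <- data.frame(class = NA_integer_, label = "suitable",
                     nhs_km2 = sum(tab$nhs_km2[tab$class >= 2]),
                     pcs_km2 = sum(tab$pcs_km2[tab$class >= 2]))
  tab <- rbind(tab, suit)
  tab$difference_rate <- suppressWarnings(
    area_difference_rate(tab$pcs_km2, tab$nhs_km2))

  cen_nhs <- tryCatch(suitable_centroid(bin_nhs, areas_km2),
                      error = function(e) c(lon = NA_real_, lat = NA_real_))
  cen_pcs <- tryCatch(suitable_centroid(bin_pcs, areas_km2),
                      error = function(e) c(lon = NA_real_, lat = NA_real_))
  shift <- if (anyNA(c(cen_nhs, cen_pcs))) c(distance_km = NA_real_,
                                             bearing_deg = NA_real_)
           else centroid_shift(cen_nhs, cen_pcs)

  structure(list(class_areas = tab,
                 centroids = list(nhs = cen_nhs, pcs = cen_pcs),
                 centroid_shift_km = unname(shift["distance_km"]),
                 centroid_bearing_deg = unname(shift["bearing_deg"]),
                 layers = list(p_nhs = p_nhs, p_pcs = p_pcs, p_ha = p_ha),
                 reports = list(host = host_report, nhs = nhs_fit$report,
                                pcs = pcs_fit$report),
                 fits = list(host = host_models, nhs = nhs_fit$models,
                             pcs = pcs_fit$models),
                 theta = theta, breaks = breaks, seed = seed),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> theta = %g\n", x$theta))
  t <- x$class_areas
  t$nhs_km2 <- round(t$nhs_km2, 1); t$pcs_km2 <- round(t$pcs_km2, 1)
  t$difference_rate <- round(t$difference_rate, 2)
  print(t, row.names = FALSE)
  if (is.finite(x$centroid_shift_km))
    cat(sprintf("centroid shift %.1f km (bearing %.0f deg)\n",
                x$centroid_shift_km, x$centroid_bearing_deg))
  invisible(x)
}

#' Write a scenario comparison as delimited text
#' @param comparison a `scenario_comparison`.
#' @param path output path.
#' @export
write_scenario_comparison <- function(comparison, path) {
  utils::write.table(comparison$class_areas, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
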