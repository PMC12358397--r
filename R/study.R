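#' Default study configuration
#'
#' Defaults mirror the standard two-scenario workflow: RM grid 0.5-4 step
#' 0.5, the six feature combinations, 10 replicates, 75/25 train/test
#' split, parasitism threshold 0.4 and classification breaks 0.2/0.4/0.6.
#'
#' @return named list of defaults.
#' @export
default_study_config <- function() {
  list(occurrences = NULL, host_occurrences = NULL,
       env = NULL, landuse = NULL, future = NULL,
       tune = FALSE,
       fcs = c("l", "lq", "lqh", "h", "lqhp", "lqhpt"),
       rms = seq(0.5, 4, by = 0.5),
       fc = "lq", rm = 1, host_fc = "lqhpt", host_rm = 2.5,
       theta = 0.4, breaks = c(0.2, 0.4, 0.6),
       r_threshold = 0.8, select_variables = TRUE,
       replicates = 10, n_background = 10000, test_fraction = 0.25,
       seed = 1, out = "study_out")
}

#' Read a study configuration file
#'
#' YAML key-value file; unset keys take the defaults of
#' [default_study_config()].
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_study_config <- function(path) {
  cfg <- utils::modifyList(default_study_config(), yaml::read_yaml(path))
  validate_study_config(cfg)
}

#' Validate a study configuration
#' @param cfg config list.
#' @return the config, invisibly checked.
#' @export
validate_study_config <- function(cfg) {
  if (!(cfg$theta > 0 && cfg$theta < 1))
    stop("config error: theta must lie in (0, 1)")
  if (length(cfg$breaks) != 3 || any(diff(cfg$breaks) <= 0) ||
      any(cfg$breaks <= 0 | cfg$breaks >= 1))
    stop("config error: breaks must be three increasing values in (0, 1)")
  for (p in list(cfg$occurrences, cfg$host_occurrences))
    if (is.character(p) && !file.exists(p)) stop("missing file: ", p)
  cfg
}

.load_layers <- function(x) {
  if (is.null(x)) return(NULL)
  if (all(vapply(x, inherits, TRUE, "grid_layer"))) return(x)
  out <- lapply(x, read_ascii_grid)
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- sub("\\.asc$", "", basename(unlist(x)))
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("study stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full two-scenario habitat study
#'
#' Orchestrates the pipeline end to end: occurrence thinning, collinearity
#' filtering, host model, Natural Habitat and Parasitic Constraint
#' scenarios, four-level classification with areas, optional future-period
#' projection with change maps and centroid shifts, optional land-use
#' overlay, and a run manifest. All outputs are plain text (ASCII grids,
#' TSV tables) under `cfg$out`; a stage failure aborts with the stage name
#' and retains partial outputs.
#'
#' @param cfg config list (see [default_study_config()]); `occurrences`,
#'   `host_occurrences` may be file paths or `occurrences` objects; `env`
#'   a named list of `.asc` paths or `grid_layer`s; `future` an optional
#'   named list (period -> env list); `landuse` an optional
#'   `land_use_layer` or path.
#' @return invisibly, a list with the main intermediate objects
#'   (`comparison`, `selection`, `occ`, `host_occ`, `periods`, `manifest`).
#' @export
run_study <- function(cfg) {
  cfg <- validate_study_config(utils::modifyList(default_study_config(), cfg))
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out, "run.log")
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg); cat(msg, "\n", file = log_path, append = TRUE)
  }

  env <- .stage("load_env", {
    e <- .load_layers(cfg$env)
    if (is.null(e)) stop("no predictor layers configured")
    assert_coregistered(e); e
  })
  mask <- valid_mask(env)

  occ <- .stage("occurrences", {
    o <- if (is.character(cfg$occurrences)) read_occurrences(cfg$occurrences)
         else cfg$occurrences
    o <- thin_to_grid(filter_to_region(deduplicate(o), mask), env[[1]])
    write_occurrences(o, file.path(cfg$out, "occurrences_thinned.csv"))
    o
  })
  host_occ <- .stage("host_occurrences", {
    o <- if (is.character(cfg$host_occurrences))
      read_occurrences(cfg$host_occurrences) else cfg$host_occurrences
    if (is.null(o)) stop("host occurrences are required")
    o <- thin_to_grid(filter_to_region(deduplicate(o), mask), env[[1]])
    write_occurrences(o, file.path(cfg$out, "host_occurrences_thinned.csv"))
    o
  })
  logmsg("thinned: %d parasite, %d host records", nrow(occ), nrow(host_occ))

  selection <- NULL
  if (isTRUE(cfg$select_variables) && length(env) >= 2) {
    selection <- .stage("variable_selection", {
      prelim <- replicate_fit(occ, env, feature_spec(cfg$fc), cfg$rm,
                              n_replicates = 1,
                              n_background = cfg$n_background,
                              test_fraction = cfg$test_fraction,
                              seed = cfg$seed + 10L)
      bg <- sample_background(mask, cfg$n_background, seed = cfg$seed + 10L)
      contrib <- permutation_importance(
        prelim$models[[1]],
        extract_values(env, occ$lon, occ$lat),
        extract_values(env, bg$lon, bg$lat), seed = cfg$seed + 11L)
      rep <- select_variables(env, contrib, cfg$r_threshold)
      write_selection_report(rep, file.path(cfg$out, "variable_selection.tsv"))
      rep
    })
    env <- env[selection$kept]
    logmsg("variable selection kept %d of %d layers", length(env),
           nrow(selection$correlation))
  }

  fc <- cfg$fc; rmv <- cfg$rm; host_fc <- cfg$host_fc; host_rm <- cfg$host_rm
  if (isTRUE(cfg$tune)) {
    tun <- .stage("tuning", {
      t1 <- tune_maxent(occ, env, cfg$fcs, cfg$rms,
                        n_background = cfg$n_background,
                        test_fraction = cfg$test_fraction, seed = cfg$seed)
      write_tuning_table(t1, file.path(cfg$out, "tuning_parasite.tsv"))
      t2 <- tune_maxent(host_occ, env, cfg$fcs, cfg$rms,
                        n_background = cfg$n_background,
                        test_fraction = cfg$test_fraction, seed = cfg$seed)
      write_tuning_table(t2, file.path(cfg$out, "tuning_host.tsv"))
      list(parasite = t1, host = t2)
    })
    fc <- tun$parasite$selected$fc; rmv <- tun$parasite$selected$rm
    host_fc <- tun$host$selected$fc; host_rm <- tun$host$selected$rm
    logmsg("tuned: parasite FC=%s RM=%g; host FC=%s RM=%g", fc, rmv,
           host_fc, host_rm)
  }

  comparison <- .stage("two_scenarios", {
    cmp <- run_two_scenarios(
      occ, env, host_occ, spec = feature_spec(fc), rm = rmv,
      host_spec = feature_spec(host_fc), host_rm = host_rm,
      theta = cfg$theta, breaks = cfg$breaks,
      n_replicates = cfg$replicates, n_background = cfg$n_background,
      test_fraction = cfg$test_fraction, seed = cfg$seed)
    write_ascii_grid(cmp$layers$p_nhs, file.path(cfg$out, "suitability_nhs.asc"))
    write_ascii_grid(cmp$layers$p_pcs, file.path(cfg$out, "suitability_pcs.asc"))
    write_ascii_grid(cmp$layers$p_ha, file.path(cfg$out, "suitability_host.asc"))
    write_scenario_comparison(cmp, file.path(cfg$out, "scenario_comparison.tsv"))
    cmp
  })
  logmsg("scenario comparison written (theta = %g)", cfg$theta)

  areas_km2 <- cell_area_layer(env[[1]])
  periods <- list(current = list(nhs = comparison$layers$p_nhs,
                                 pcs = comparison$layers$p_pcs))
  if (!is.null(cfg$future)) {
    periods <- c(periods, .stage("future_projection", {
      fits <- comparison$fits
      out <- lapply(names(cfg$future), function(per) {
        fenv <- .load_layers(cfg$future[[per]])
        fenv <- fenv[names(env)]
        assert_coregistered(c(list(env[[1]]), fenv))
        mean_pred <- function(models, layers) {
          acc <- NULL
          for (m in models) {
            p <- predict(m, layers, type = "logistic")
            acc <- if (is.null(acc)) p$values else acc + p$values
          }
          g <- layers[[1]]
          grid_layer(acc / length(models), g$xll, g$yll, g$cellsize,
                     g$nodata_value, "continuous")
        }
        p_ha_f <- mean_pred(fits$host, fenv)
        p_nhs_f <- mean_pred(fits$nhs, fenv)
        p_pcs_f <- conditional_probability_transfer(
          mean_pred(fits$pcs, build_pcs_predictors(fenv, p_ha_f)),
          p_ha_f, cfg$theta)
        write_ascii_grid(p_nhs_f, file.path(cfg$out,
                                            sprintf("suitability_nhs_%s.asc", per)))
        write_ascii_grid(p_pcs_f, file.path(cfg$out,
                                            sprintf("suitability_pcs_%s.asc", per)))
        list(nhs = p_nhs_f, pcs = p_pcs_f)
      })
      names(out) <- names(cfg$future)
      out
    }))
    .stage("change_analysis", {
      rows <- list()
      for (scn in c("nhs", "pcs")) {
        b0 <- binarize(periods$current[[scn]], cfg$theta)
        for (per in setdiff(names(periods), "current")) {
          b1 <- binarize(periods[[per]][[scn]], cfg$theta)
          ch <- change_map(b0, b1, areas_km2)
          write_ascii_grid(ch$map, file.path(cfg$out,
                                             sprintf("change_%s_%s.asc", scn, per)))
          cen0 <- suitable_centroid(b0, areas_km2)
          cen1 <- suitable_centroid(b1, areas_km2)
          sh <- centroid_shift(cen0, cen1)
          rows[[length(rows) + 1]] <- cbind(
            data.frame(scenario = scn, period = per), t(ch$areas$area_km2) |>
              as.data.frame() |> stats::setNames(ch$areas$category),
            data.frame(centroid_lon = cen1["lon"], centroid_lat = cen1["lat"],
                       shift_km = sh["distance_km"],
                       bearing_deg = sh["bearing_deg"]))
        }
      }
      utils::write.table(do.call(rbind, rows),
                         file.path(cfg$out, "change_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    })
    logmsg("future periods projected: %s",
           paste(setdiff(names(periods), "current"), collapse = ", "))
  }

  if (!is.null(cfg$landuse)) {
    .stage("landuse_overlay", {
      lu <- if (inherits(cfg$landuse, "land_use_layer")) cfg$landuse
            else land_use_layer(read_ascii_grid(cfg$landuse, "categorical"))
      bins <- lapply(periods, function(p) binarize(p$pcs, cfg$theta))
      stable <- if (length(bins) >= 2) stable_suitable(bins) else bins[[1]]
      write_ascii_grid(stable, file.path(cfg$out, "stable_suitable.asc"))
      comp <- landuse_composition(stable, lu, areas_km2)
      comp$share_of_class <- vapply(comp$class, function(cl)
        tryCatch(class_share_inside(stable, lu, cl, areas_km2),
                 error = function(e) NA_real_), 0)
      utils::write.table(comp, file.path(cfg$out, "landuse_composition.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      trend <- suitable_area_by_landuse(
        stats::setNames(lapply(periods, `[[`, "pcs"), names(periods)),
        lu, areas_km2, cfg$theta)
      utils::write.table(trend, file.path(cfg$out, "landuse_trend.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    })
    logmsg("land-use overlay written")
  }

  manifest <- c(
    sprintf("hostSDM %s on R %s", as.character(utils::packageVersion("hostSDM")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed\t%d", cfg$seed),
    sprintf("theta\t%g", cfg$theta),
    sprintf("breaks\t%s", paste(cfg$breaks, collapse = " ")),
    sprintf("fc\t%s", fc), sprintf("rm\t%g", rmv),
    sprintf("host_fc\t%s", host_fc), sprintf("host_rm\t%g", host_rm),
    sprintf("replicates\t%d", cfg$replicates),
    sprintf("n_background\t%d", cfg$n_background),
    sprintf("test_fraction\t%g", cfg$test_fraction),
    sprintf("predictors\t%s", paste(names(env), collapse = " ")),
    sprintf("tuned\t%s", isTRUE(cfg$tune)))
  writeLines(manifest, file.path(cfg$out, "manifest.txt"))
  logmsg("study complete: %s", cfg$out)
  invisible(list(comparison = comparison, selection = selection, occ = occ,
                 host_occ = host_occ, periods = periods, manifest = manifest))
}
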