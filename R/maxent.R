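#' Fit a maximum-entropy (Gibbs) species distribution model
#'
#' Presence-background MaxEnt: the model is the Gibbs density
#' `raw(x) = exp(lambda . f(x)) / Z` over landscape cells, with `Z`
#' normalizing over the background sample. Coefficients maximize the
#' penalized log likelihood
#' `mean_presence(lambda . f) - log sum_background exp(lambda . f) -
#'  sum_j beta_j |lambda_j|`,
#' where the per-feature penalty widths `beta_j` follow the reference
#' default schedule for the feature's class, scaled linearly by the
#' regularization multiplier `rm` (see `R/regularization.R`). Optimization
#' is monotone proximal gradient (soft-thresholding step on the L1 term)
#' with backtracking line search, so the penalized objective never
#' decreases across iterations.
#'
#' @param presence data.frame of raw predictor values at presence cells.
#' @param background data.frame of raw predictor values at background cells
#'   (same columns). Feature scaling ranges are taken from the background.
#' @param features a [feature_spec()]; default linear + quadratic.
#' @param rm regularization multiplier (> 0).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence yields a warning and
#'   `converged = FALSE`.
#'
#' @return An object of class `maxent` with elements `lambda`
#'   (coefficients over expanded features), `beta` (penalties), `scaling`,
#'   `features`, `rm`, `log_normalizer` (log Z over the background),
#'   `entropy` (Shannon entropy, nats, of the fitted background
#'   distribution), `gain` (regularized training gain), `n_presence`,
#'   `n_background`, `k_nonzero` (coefficients with |lambda| > 1e-7),
#'   `converged` and `objective` (per-iteration trace).
#' @seealso [predict.maxent()], [tune_maxent()], [replicate_fit()]
#' @export
maxent <- function(presence, background, features = feature_spec("lq"),
                   rm = 1, tol = 1e-7, max_iter = 10000L) {
  stopifnot(inherits(features, "feature_spec"), rm > 0)
  presence <- as.data.frame(presence)
  background <- as.data.frame(background)
  if (nrow(presence) < 2) stop("need at least 2 presence records")
  if (nrow(background) < 1) stop("background must be non-empty")
  presence <- presence[stats::complete.cases(presence), , drop = FALSE]
  background <- background[stats::complete.cases(background), , drop = FALSE]
  scaling <- feature_scaling(background)
  Fp <- expand_features(presence, features, scaling)
  Fb <- expand_features(background, features, scaling)
  if (all(apply(Fp, 2, function(x) max(x) - min(x)) < 1e-12))
    warning("all presence feature vectors are identical; fit is degenerate")
  m <- nrow(Fp); n <- nrow(Fb); d <- ncol(Fb)
  beta <- regularization_beta(attr(Fb, "feature_class"), Fb, m, rm)
  fbar <- colMeans(Fp)

  logsumexp <- function(x) { mx <- max(x); mx + log(sum(exp(x - mx))) }
  smooth_neg <- function(lam) {
    # f(lam) = -mean_p(F lam) + log sum_b exp(F lam)  (to be minimized)
    eta <- drop(Fb %*% lam)
    -sum(fbar * lam) + logsumexp(eta)
  }
  objective <- function(lam) -(smooth_neg(lam) + sum(beta * abs(lam)))

  lam <- numeric(d)
  obj_trace <- numeric(0)
  f_cur <- smooth_neg(lam)
  F_cur <- -(f_cur + 0)
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Fb %*% lam)
    w <- exp(eta - max(eta)); q <- w / sum(w)
    grad <- -fbar + drop(crossprod(Fb, q))
    repeat {
      cand <- lam - step * grad
      cand <- sign(cand) * pmax(abs(cand) - step * beta, 0)
      dlt <- cand - lam
      f_new <- smooth_neg(cand)
      if (f_new <= f_cur + sum(grad * dlt) + sum(dlt^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) { cand <- lam; f_new <- f_cur; break }
    }
    lam <- cand; f_cur <- f_new
    F_new <- objective(lam)
    obj_trace <- c(obj_trace, F_new)
    if (it > 1 && abs(F_new - F_cur) <= tol * max(1, abs(F_new))) {
      # objective has flattened; accept only once the KKT subgradient
      # conditions hold, otherwise a flat stretch could stop us early
      eta2 <- drop(Fb %*% lam)
      w2 <- exp(eta2 - max(eta2)); q2 <- w2 / sum(w2)
      g2 <- -fbar + drop(crossprod(Fb, q2))
      kkt <- ifelse(abs(lam) > 1e-12,
                    abs(g2 + sign(lam) * beta),
                    pmax(abs(g2) - beta, 0))
      if (max(kkt) < 2e-6) {
        converged <- TRUE
        F_cur <- F_new
        break
      }
    }
    F_cur <- F_new
    step <- step * 1.5
  }
  if (!converged) warning("maxent fit did not converge in ", max_iter, " iterations")

  eta <- drop(Fb %*% lam)
  logZ <- logsumexp(eta)
  q <- exp(eta - logZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  gain <- sum(fbar * lam) - logZ + log(n)

  structure(list(lambda = stats::setNames(lam, colnames(Fb)), beta = beta,
                 features = features, rm = rm, scaling = scaling,
                 variable_names = scaling$var,
                 bg_means = colMeans(background[, scaling$var, drop = FALSE]),
                 log_normalizer = logZ, entropy = H, gain = gain,
                 n_presence = m, n_background = n,
                 k_nonzero = sum(abs(lam) > 1e-7),
                 converged = converged, objective = obj_trace,
                 n_clamped_train = attr(Fp, "n_clamped")),
            class = "maxent")
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf("<maxent %s, rm = %g> %d presences, %d background cells\n",
              x$features$label, x$rm, x$n_presence, x$n_background))
  cat(sprintf("  %d / %d non-zero coefficients; entropy %.4f nats; gain %.4f%s\n",
              x$k_nonzero, length(x$lambda), x$entropy, x$gain,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$lambda

#' @export
summary.maxent <- function(object, ...) {
  nz <- abs(object$lambda) > 1e-7
  out <- list(model = object,
              coefficients = data.frame(feature = names(object$lambda)[nz],
                                        lambda = unname(object$lambda[nz]),
                                        beta = unname(object$beta[nz])))
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  if (nrow(x$coefficients)) {
    cat("Non-zero coefficients:\n")
    print(x$coefficients, row.names = FALSE)
  }
  invisible(x)
}

#' Predict from a fitted maxent model
#'
#' `type = "raw"` gives the Gibbs density `exp(lambda . f(x)) / Z` with `Z`
#' fixed at its training-background value, so raw predictions sum to 1 over
#' the training background. `type = "logistic"` applies the entropy-based
#' transform `p = exp(H) raw / (1 + exp(H) raw)`, the suitability index in
#' [0, 1]. `type = "link"` returns `lambda . f(x)`. Features are clamped to
#' the training [0, 1] range.
#'
#' @param object a `maxent` fit.
#' @param newdata a data.frame of raw predictor values, or a named list of
#'   co-registered `grid_layer`s (one per variable), in which case a
#'   `grid_layer` is returned.
#' @param type `"logistic"`, `"raw"` or `"link"`.
#' @param ... unused.
#' @return numeric vector, or `grid_layer` when `newdata` is a layer list.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("logistic", "raw", "link"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && all(vapply(newdata, inherits, TRUE, "grid_layer"))) {
    layers <- newdata
    assert_coregistered(layers)
    g <- layers[[1]]
    valid <- Reduce(`&`, lapply(layers, function(l) is.finite(l$values)))
    df <- as.data.frame(lapply(layers, function(l) l$values[valid]),
                        optional = TRUE)
    names(df) <- names(layers)
    p <- predict.maxent(object, df, type = type)
    out <- matrix(NA_real_, g$nrows, g$ncols)
    out[valid] <- p
    return(grid_layer(out, g$xll, g$yll, g$cellsize, g$nodata_value, "continuous"))
  }
  F <- expand_features(as.data.frame(newdata), object$features, object$scaling)
  link <- drop(F %*% object$lambda)
  if (type == "link") return(link)
  raw <- exp(link - object$log_normalizer)
  if (type == "raw") return(raw)
  er <- exp(object$entropy) * raw
  er / (1 + er)
}

#' Simulate presence cells from a fitted model
#'
#' Draws rows of `newdata` with probability proportional to the fitted Gibbs
#' density, emulating presence sampling from the estimated distribution.
#'
#' @param object a `maxent` fit.
#' @param nsim number of replicate draws.
#' @param seed optional integer seed (RNG state is restored).
#' @param newdata data.frame of raw predictor values to sample from.
#' @param size draws per replicate.
#' @param replace sample with replacement (default TRUE).
#' @param ... unused.
#' @return data.frame with `nsim` columns of sampled row indices.
#' @export
simulate.maxent <- function(object, nsim = 1, seed = NULL, newdata,
                            size = object$n_presence, replace = TRUE, ...) {
  raw <- predict.maxent(object, newdata, type = "raw")
  draws <- with_seed(seed, {
    replicate(nsim, sample.int(length(raw), size, replace = replace,
                               prob = raw), simplify = FALSE)
  })
  out <- as.data.frame(draws, optional = TRUE)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Response curves of a fitted model
#'
#' One panel per variable: suitability as the variable sweeps its training
#' range with all other variables held at their background means.
#'
#' @param x a `maxent` fit.
#' @param n_points grid points per curve.
#' @param ... passed to [graphics::plot()].
#' @export
plot.maxent <- function(x, n_points = 100, ...) {
  vars <- x$variable_names
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(vars)))
  on.exit(graphics::par(old))
  for (v in vars) {
    sc <- x$scaling[x$scaling$var == v, ]
    grid <- seq(sc$min, sc$max, length.out = n_points)
    nd <- as.data.frame(lapply(x$bg_means, rep, n_points))
    nd[[v]] <- grid
    p <- predict.maxent(x, nd, type = "logistic")
    graphics::plot(grid, p, type = "l", xlab = v, ylab = "suitability",
                   ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Serialize a fitted model to plain text
#'
#' Versioned key-value format; reload with [read_maxent()].
#'
#' @param model a `maxent` fit.
#' @param path output path.
#' @export
write_maxent <- function(model, path) {
  num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  lines <- c("hostSDM-maxent v1",
             paste("classes", paste(model$features$classes, collapse = "")),
             paste("hinge_knots", model$features$hinge_knots),
             paste("threshold_knots", model$features$threshold_knots),
             paste("rm", num(model$rm)),
             paste("variables", paste(model$variable_names, collapse = " ")),
             paste("scaling_min", num(model$scaling$min)),
             paste("scaling_max", num(model$scaling$max)),
             paste("bg_means", num(model$bg_means)),
             paste("lambda", num(model$lambda)),
             paste("beta", num(model$beta)),
             paste("log_normalizer", num(model$log_normalizer)),
             paste("entropy", num(model$entropy)),
             paste("gain", num(model$gain)),
             paste("n_presence", model$n_presence),
             paste("n_background", model$n_background),
             paste("converged", as.integer(model$converged)))
  writeLines(lines, path)
  invisible(NULL)
}

#' Reload a serialized maxent model
#' @param path path written by [write_maxent()].
#' @return A `maxent` object (without the optimization trace).
#' @export
read_maxent <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (lines[1] != "hostSDM-maxent v1") stop("unrecognized model file header")
  kv <- strsplit(trimws(lines[-1]), "\\s+")
  keys <- vapply(kv, `[[`, "", 1)
  val <- function(k) kv[[which(keys == k)[1]]][-1]
  num <- function(k) as.numeric(val(k))
  vars <- val("variables")
  spec <- feature_spec(val("classes"), as.integer(val("hinge_knots")),
                       as.integer(val("threshold_knots")))
  scaling <- data.frame(var = vars, min = num("scaling_min"),
                        max = num("scaling_max"), stringsAsFactors = FALSE)
  lam <- num("lambda")
  # recover feature names via a dummy expansion
  Fd <- expand_features(as.data.frame(stats::setNames(as.list(scaling$min), vars)),
                        spec, scaling)
  structure(list(lambda = stats::setNames(lam, colnames(Fd)), beta = num("beta"),
                 features = spec, rm = num("rm"), scaling = scaling,
                 variable_names = vars,
                 bg_means = stats::setNames(num("bg_means"), vars),
                 log_normalizer = num("log_normalizer"), entropy = num("entropy"),
                 gain = num("gain"),
                 n_presence = as.integer(val("n_presence")),
                 n_background = as.integer(val("n_background")),
                 k_nonzero = sum(abs(lam) > 1e-7),
                 converged = as.logical(as.integer(val("converged"))),
                 objective = numeric(0), n_clamped_train = NA_integer_),
            class = "maxent")
}

#' Sample background cells from a region mask
#'
#' Uniform sample without replacement of valid `mask == 1` cells; when `n`
#' meets or exceeds the number of valid cells, all of them are returned.
#'
#' @param mask a binary `grid_layer`.
#' @param n sample size.
#' @param seed integer seed (RNG state restored).
#' @return data.frame with `row`, `col`, `lon`, `lat` of sampled cell
#'   centers.
#' @export
sample_background <- function(mask, n = 10000, seed = NULL) {
  stopifnot(inherits(mask, "grid_layer"))
  ok <- which(is.finite(mask$values) & mask$values == 1, arr.ind = TRUE)
  if (!nrow(ok)) stop("mask has no valid cells")
  idx <- if (n >= nrow(ok)) seq_len(nrow(ok)) else
    with_seed(seed, sample.int(nrow(ok), n))
  cc <- cell_centers(mask)
  data.frame(row = ok[idx, 1], col = ok[idx, 2],
             lon = cc$lon[ok[idx, 2]], lat = cc$lat[ok[idx, 1]])
}

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
# Relies on lazy evaluation: expr is forced only after set.seed().
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}
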