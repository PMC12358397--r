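#' Blank grid template
#'
#' Convenience constructor for a study grid: an all-valid continuous layer
#' of zeros.
#'
#' @param nrows,ncols grid dimensions.
#' @param xll,yll lower-left corner (degrees).
#' @param cellsize cell size (degrees); default 2.5 arc-minutes.
#' @return continuous `grid_layer`.
#' @export
grid_template <- function(nrows, ncols, xll = 75, yll = 35,
                          cellsize = 2.5 / 60) {
  grid_layer(matrix(0, nrows, ncols), xll, yll, cellsize)
}

# Gaussian smoothing of a matrix by separable row/column convolution,
# edge-renormalized so the mean level is preserved at the borders.
.smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  sm1 <- function(x) {
    n <- length(x)
    xp <- c(rep(x[1], half), x, rep(x[n], half))
    stats::convolve(xp, rev(k), type = "filter") / sum(k)
  }
  m <- apply(m, 2, sm1)
  t(apply(m, 1, sm1))
}

#' Generate spatially autocorrelated synthetic predictor layers
#'
#' Gaussian random fields built by smoothing white noise with a Gaussian
#' kernel of width `smoothness` cells; inter-layer correlation is induced
#' by mixing a shared latent field into each layer with weight
#' `sqrt(pairwise_r)`. Each layer is linearly rescaled to [0, 1] (which
#' preserves correlations).
#'
#' @param template a `grid_layer` defining the grid (nodata cells are
#'   copied through).
#' @param n_layers number of layers (>= 1).
#' @param smoothness kernel standard deviation in cells; 0 = white noise.
#' @param pairwise_r target pairwise correlation in [0, 1).
#' @param seed integer seed (RNG state restored).
#' @return named list (`env1`, `env2`, ...) of continuous `grid_layer`s.
#' @export
generate_env_layers <- function(template, n_layers, smoothness = 5,
                                pairwise_r = 0, seed = 1) {
  stopifnot(n_layers >= 1, abs(pairwise_r) < 1, pairwise_r >= 0)
  nr <- template$nrows; nc <- template$ncols
  with_seed(seed, {
    shared <- .smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), smoothness)
    shared <- shared / stats::sd(shared)
    out <- lapply(seq_len(n_layers), function(i) {
      f <- .smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), smoothness)
      f <- f / stats::sd(f)
      g <- sqrt(pairwise_r) * shared + sqrt(1 - pairwise_r) * f
      g <- (g - min(g)) / (max(g) - min(g))
      g[!is.finite(template$values)] <- NA_real_
      grid_layer(g, template$xll, template$yll, template$cellsize,
                 template$nodata_value, "continuous")
    })
    names(out) <- paste0("env", seq_len(n_layers))
    out
  })
}

#' Define a virtual species from a linear + quadratic response
#'
#' Truth is the inverse-logit of `intercept + sum(linear_i * env_i) +
#' sum(quadratic_i * env_i^2)` evaluated cellwise on the (already [0, 1])
#' predictor layers.
#'
#' @param env_layers named list of `grid_layer`s.
#' @param linear named coefficients on the linear terms (subset of layers).
#' @param quadratic named coefficients on the squared terms.
#' @param intercept scalar.
#' @return A `virtual_species`: `truth` (`grid_layer` in [0, 1]),
#'   `linear`, `quadratic`, `intercept`, `host_mask_threshold` (NULL).
#' @export
make_virtual_species <- function(env_layers, linear = numeric(),
                                 quadratic = numeric(), intercept = 0) {
  bad <- setdiff(c(names(linear), names(quadratic)), names(env_layers))
  if (length(bad)) stop("coefficients reference absent layers: ",
                        paste(bad, collapse = ", "))
  assert_coregistered(env_layers)
  g <- env_layers[[1]]
  eta <- matrix(intercept, g$nrows, g$ncols)
  for (v in names(linear)) eta <- eta + linear[[v]] * env_layers[[v]]$values
  for (v in names(quadratic)) eta <- eta + quadratic[[v]] * env_layers[[v]]$values^2
  truth <- grid_layer(stats::plogis(eta), g$xll, g$yll, g$cellsize,
                      g$nodata_value, "continuous")
  structure(list(truth = truth, linear = linear, quadratic = quadratic,
                 intercept = intercept, host_mask_threshold = NULL),
            class = "virtual_species")
}

#' @export
print.virtual_species <- function(x, ...) {
  cat("<virtual_species>",
      if (is.null(x$host_mask_threshold)) "free-living"
      else sprintf("host-masked at %g", x$host_mask_threshold), "\n")
  print(x$truth)
  invisible(x)
}

#' Derive a host-masked parasite from a host species
#'
#' The parasite's environmental response (same linear + quadratic form) is
#' multiplied by the indicator `host truth >= theta_true`, so true
#' parasite suitability is zero wherever the host is (truly) unsuitable —
#' the ground-truth analogue of the conditional probability transfer.
#'
#' @param host a `virtual_species` (the host).
#' @param env_layers named list of `grid_layer`s.
#' @param linear,quadratic,intercept the parasite's environmental response.
#' @param theta_true host-truth threshold (default 0.4).
#' @return A `virtual_species` with `host_mask_threshold` set.
#' @export
make_parasite <- function(host, env_layers, linear = numeric(),
                          quadratic = numeric(), intercept = 0,
                          theta_true = 0.4) {
  stopifnot(inherits(host, "virtual_species"))
  env_resp <- make_virtual_species(env_layers, linear, quadratic, intercept)
  assert_coregistered(list(env_resp$truth, host$truth))
  v <- env_resp$truth$values * (host$truth$values >= theta_true)
  g <- env_resp$truth
  structure(list(truth = grid_layer(v, g$xll, g$yll, g$cellsize,
                                    g$nodata_value, "continuous"),
                 linear = linear, quadratic = quadratic,
                 intercept = intercept, host_mask_threshold = theta_true),
            class = "virtual_species")
}

#' Sample presence points from a virtual species
#'
#' Draws `n` cells without replacement with probability proportional to the
#' truth layer and places one point at each cell center.
#'
#' @param species a `virtual_species` (truth must have positive mass).
#' @param n number of points.
#' @param seed integer seed (RNG state restored).
#' @param species_name species label on the records.
#' @return An `occurrences` object.
#' @export
sample_occurrences <- function(species, n, seed = NULL,
                               species_name = "virtual") {
  truth <- species$truth
  w <- truth$values
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) stop("truth layer has no positive mass")
  pos <- which(w > 0)
  if (n > length(pos))
    stop("cannot draw ", n, " cells without replacement from ",
         length(pos), " positive cells")
  idx <- with_seed(seed, sample(pos, n, replace = FALSE, prob = w[pos]))
  rc <- arrayInd(idx, dim(w))
  cc <- cell_centers(truth)
  occurrences(species_name, cc$lon[rc[, 2]], cc$lat[rc[, 1]],
              source = "synthetic")
}

#' Canonical synthetic host-parasite study system
#'
#' One call builds the standard test landscape: four smoothed random
#' predictor layers on a 100 x 100 grid at 2.5 arc-minutes, a host species
#' with a unimodal linear + quadratic niche on `env1`/`env2`, a parasite
#' whose true suitability is its own `env2`/`env3` niche masked to zero
#' where host truth falls below `theta_true`, and presence samples of 234
#' host and 200 parasite points (mirroring a realistic occurrence-data
#' footprint after thinning). All niche coefficients are fixed so the
#' system has a strong, recoverable signal.
#'
#' @param nrows,ncols grid size.
#' @param n_env number of predictor layers (>= 3).
#' @param smoothness field correlation length in cells.
#' @param n_host,n_parasite presence sample sizes.
#' @param theta_true host-truth masking threshold.
#' @param seed master integer seed.
#' @return list: `env` (layer list), `host`, `parasite`
#'   (`virtual_species`), `host_occ`, `parasite_occ` (`occurrences`).
#' @export
synthetic_study <- function(nrows = 100, ncols = 100, n_env = 4,
                            smoothness = 8, n_host = 234, n_parasite = 200,
                            theta_true = 0.4, seed = 1) {
  stopifnot(n_env >= 3)
  tpl <- grid_template(nrows, ncols)
  env <- generate_env_layers(tpl, n_env, smoothness, seed = seed)
  # Unimodal niches are anchored to each realized field's mean and spread,
  # eta = b0 - sum_i b_i ((u_i - c_i) / s_i)^2, so that the suitable
  # fraction of the landscape is stable across random realizations (a
  # min/max-rescaled field shifts its distribution from seed to seed).
  niche <- function(vars, b, centers_sd, b0) {
    lin <- quad <- numeric(); icpt <- b0
    for (i in seq_along(vars)) {
      v <- env[[vars[i]]]$values
      s <- stats::sd(v)
      c_i <- mean(v) + centers_sd[i] * s
      quad[vars[i]] <- -b[i] / s^2
      lin[vars[i]] <- 2 * b[i] * c_i / s^2
      icpt <- icpt - b[i] * c_i^2 / s^2
    }
    list(linear = lin, quadratic = quad, intercept = icpt)
  }
  h <- niche(c("env1", "env2"), b = c(12, 10), centers_sd = c(0.2, 0),
             b0 = 3)
  host <- make_virtual_species(env, h$linear, h$quadratic, h$intercept)
  p <- niche(c("env2", "env3"), b = c(10, 10), centers_sd = c(0.3, 0),
             b0 = 3.5)
  parasite <- make_parasite(host, env, p$linear, p$quadratic, p$intercept,
                            theta_true = theta_true)
  list(env = env, host = host, parasite = parasite,
       host_occ = sample_occurrences(host, n_host, seed + 1L, "host"),
       parasite_occ = sample_occurrences(parasite, n_parasite, seed + 2L,
                                         "parasite"))
}
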