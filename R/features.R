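#' Feature-class specification
#'
#' Which transforms of the raw predictors enter the Gibbs model: L (linear),
#' Q (quadratic), P (pairwise products), H (hinge, forward and reverse) and
#' T (threshold step indicators). Hinge and threshold features are laid on a
#' uniform knot grid over the scaled [0, 1] range of each variable.
#'
#' @param classes a string such as `"lqhpt"` or a character vector of
#'   single letters; case-insensitive.
#' @param hinge_knots knots per variable per hinge direction (>= 2).
#' @param threshold_knots threshold knots per variable (>= 2).
#' @return A `feature_spec` object.
#' @export
feature_spec <- function(classes = "lq", hinge_knots = 50, threshold_knots = 50) {
  cl <- unique(toupper(unlist(strsplit(paste(classes, collapse = ""), ""))))
  bad <- setdiff(cl, c("L", "Q", "H", "P", "T"))
  if (length(bad)) stop("unknown feature classes: ", paste(bad, collapse = ", "))
  if (!length(cl)) stop("feature class set must be non-empty")
  stopifnot(hinge_knots >= 2, threshold_knots >= 2)
  structure(list(classes = cl, hinge_knots = as.integer(hinge_knots),
                 threshold_knots = as.integer(threshold_knots),
                 label = paste(cl[order(match(cl, c("L", "Q", "H", "P", "T")))],
                               collapse = "")),
            class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("<feature_spec %s> hinge knots %d, threshold knots %d\n",
              x$label, x$hinge_knots, x$threshold_knots))
  invisible(x)
}

#' Per-variable scaling ranges from training data
#'
#' @param data data.frame or matrix of raw predictor values (background).
#' @return data.frame with columns `var`, `min`, `max`.
#' @export
feature_scaling <- function(data) {
  data <- as.data.frame(data)
  data.frame(var = names(data),
             min = vapply(data, function(v) min(v, na.rm = TRUE), 0),
             max = vapply(data, function(v) max(v, na.rm = TRUE), 0),
             stringsAsFactors = FALSE)
}

#' Expand raw predictor values into model features
#'
#' Each variable v is scaled to `u = (v - min) / (max - min)` and clamped to
#' [0, 1] (clamp count returned as an attribute). Then: L -> u; Q -> u^2;
#' P -> u_i * u_j over all variable pairs; H -> forward hinges
#' `max(0, (u - t) / (1 - t))` at knots t = (k-1)/K and reverse hinges
#' `max(0, (t - u) / t)` at knots t = k/K; T -> strict step indicators
#' `1[u > t]` at interior knots t = k/(K+1).
#'
#' A variable with `max == min` contributes constant features and is flagged
#' with a warning.
#'
#' @param data data.frame/matrix of raw values, columns named as in `scaling`.
#' @param spec a [feature_spec()].
#' @param scaling output of [feature_scaling()].
#' @return numeric matrix (rows = cells, columns = features) with attributes
#'   `feature_class` (per-column class letter), `feature_var` and
#'   `n_clamped`.
#' @export
expand_features <- function(data, spec, scaling) {
  data <- as.data.frame(data)
  vars <- scaling$var
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("scaling covers absent variables: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  U <- matrix(0, n, length(vars), dimnames = list(NULL, vars))
  n_clamped <- 0L
  for (j in seq_along(vars)) {
    rng <- scaling$max[j] - scaling$min[j]
    if (rng <= 0) {
      warning("variable '", vars[j], "' has zero training range; constant features")
      u <- rep(0.5, n)
    } else {
      u <- (data[[vars[j]]] - scaling$min[j]) / rng
      n_clamped <- n_clamped + sum(u < 0 | u > 1, na.rm = TRUE)
      u <- pmin(pmax(u, 0), 1)
    }
    U[, j] <- u
  }
  cols <- list(); classes <- character(); fvar <- character(); nms <- character()
  add <- function(m, cl, vn, nm) {
    cols[[length(cols) + 1L]] <<- m
    classes <<- c(classes, rep(cl, ncol(m)))
    fvar <<- c(fvar, rep(vn, ncol(m)))
    nms <<- c(nms, nm)
  }
  if ("L" %in% spec$classes)
    for (v in vars) add(U[, v, drop = FALSE], "L", v, v)
  if ("Q" %in% spec$classes)
    for (v in vars) add(U[, v, drop = FALSE]^2, "Q", v, paste0(v, "^2"))
  if ("P" %in% spec$classes && length(vars) >= 2) {
    prs <- utils::combn(vars, 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      add(U[, a, drop = FALSE] * U[, b, drop = FALSE], "P",
          paste(a, b, sep = "*"), paste(a, b, sep = "*"))
    }
  }
  if ("H" %in% spec$classes) {
    K <- spec$hinge_knots
    tf <- (seq_len(K) - 1) / K          # forward knots in [0, 1)
    tr <- seq_len(K) / K                # reverse knots in (0, 1]
    for (v in vars) {
      u <- U[, v]
      fw <- outer(u, tf, function(u, t) pmax(0, (u - t) / (1 - t)))
      rv <- outer(u, tr, function(u, t) pmax(0, (t - u) / t))
      add(fw, "H", v, sprintf("h(%s>%0.3g)", v, tf))
      add(rv, "H", v, sprintf("h(%s<%0.3g)", v, tr))
    }
  }
  if ("T" %in% spec$classes) {
    K <- spec$threshold_knots
    tt <- seq_len(K) / (K + 1)          # interior knots
    for (v in vars) {
      u <- U[, v]
      add(outer(u, tt, function(u, t) as.numeric(u > t)), "T", v,
          sprintf("t(%s>%0.3g)", v, tt))
    }
  }
  F <- do.call(cbind, cols)
  colnames(F) <- nms
  attr(F, "feature_class") <- classes
  attr(F, "feature_var") <- fvar
  attr(F, "n_clamped") <- n_clamped
  F
}
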