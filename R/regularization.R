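# Per-feature L1 penalty widths.
#
# The reference MaxEnt defaults tie the base penalty of each feature class
# to the presence sample size m by piecewise-linear interpolation of the
# tables below (flat beyond the last breakpoint), then scale by the
# feature's dispersion. We use
#   beta_j = rm * interp_class(m) * sd_j(background features) / sqrt(m)
# so the penalty shrinks as presences accumulate and features with wider
# spread are penalized on a comparable scale. beta is linear in the
# regularization multiplier rm.
.reg_tables <- list(
  L = list(m = c(0, 10, 30, 100), beta = c(1.00, 1.00, 0.20, 0.05)),
  Q = list(m = c(0, 10, 17, 30, 100), beta = c(1.30, 0.80, 0.50, 0.25, 0.05)),
  P = list(m = c(0, 10, 17, 30, 100), beta = c(2.60, 1.60, 0.90, 0.55, 0.05)),
  H = list(m = c(0, 1), beta = c(0.50, 0.50)),
  T = list(m = c(0, 100), beta = c(2.00, 1.00))
)

.base_regularization <- function(m, class) {
  tab <- .reg_tables[[class]]
  stats::approx(tab$m, tab$beta, xout = min(m, max(tab$m)), rule = 2)$y
}

#' Per-feature penalty vector
#'
#' @param feature_class per-feature class letters (attribute of
#'   [expand_features()]).
#' @param background_features background feature matrix (for dispersion).
#' @param m number of presence records.
#' @param rm regularization multiplier.
#' @return numeric vector of penalty widths beta_j >= 0.
#' @keywords internal
regularization_beta <- function(feature_class, background_features, m, rm) {
  sdj <- apply(background_features, 2, stats::sd)
  sdj[!is.finite(sdj) | sdj < 1e-6] <- 1e-6
  base <- vapply(feature_class, function(cl) .base_regularization(m, cl), 0)
  rm * base * sdj / sqrt(max(m, 1))
}
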