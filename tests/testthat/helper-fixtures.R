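# Small in-code fixtures shared across tests.

# a tiny all-valid template grid
tiny_grid <- function(nr = 4, nc = 5, xll = 100, yll = 40, cs = 0.5) {
  grid_layer(matrix(0, nr, nc), xll, yll, cs)
}

# a randomized continuous layer with a sprinkling of nodata
random_layer <- function(nr = 6, nc = 7, seed = 1, na_frac = 0.1) {
  set.seed(seed)
  v <- matrix(round(runif(nr * nc), 6), nr, nc)
  v[sample(length(v), floor(na_frac * length(v)))] <- NA_real_
  grid_layer(v, xll = 10, yll = -5, cellsize = 0.25)
}

# wrap a plain matrix (values in [0,1]) as a layer on a shared grid
as_layer <- function(m, kind = "continuous", xll = 80, yll = 30, cs = 0.1) {
  grid_layer(m, xll, yll, cs, kind = kind)
}

# unimodal species anchored to the realized field moments:
# eta = b0 - sum_i b_i ((u_i - mean_i) / sd_i)^2
anchored_species <- function(env, vars, b, b0 = 3) {
  lin <- quad <- numeric(); icpt <- b0
  for (i in seq_along(vars)) {
    v <- env[[vars[i]]]$values
    s <- sd(v); c_i <- mean(v)
    quad[vars[i]] <- -b[i] / s^2
    lin[vars[i]] <- 2 * b[i] * c_i / s^2
    icpt <- icpt - b[i] * c_i^2 / s^2
  }
  make_virtual_species(env, lin, quad, icpt)
}

# small 2-predictor landscape + strong 1-variable species, used by several
# model tests
small_system <- function(seed = 11, nr = 40, nc = 40) {
  tpl <- grid_template(nr, nc)
  env <- generate_env_layers(tpl, 2, smoothness = 4, seed = seed)
  sp <- anchored_species(env, "env1", b = 10, b0 = 2)
  list(env = env, species = sp)
}
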