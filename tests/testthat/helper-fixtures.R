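# Fixture builders shared across the suite. All data are generated in code.

# 1x1-pixel cube from a single time series.
series_cube <- function(y, years = seq_along(y) + 1980L, grid = NULL) {
  if (is.null(grid)) grid <- grid_spec(1L, 1L)
  raster_cube(array(as.numeric(y), c(length(y), 1L, 1L)), years, grid)
}

# Cube from a list of per-time (row x col) matrices.
layers_cube <- function(layers, years = seq_along(layers) + 1980L, grid = NULL) {
  nr <- nrow(layers[[1L]]); nc <- ncol(layers[[1L]])
  if (is.null(grid)) grid <- grid_spec(nr, nc)
  v <- array(NA_real_, c(length(layers), nr, nc))
  for (i in seq_along(layers)) v[i, , ] <- layers[[i]]
  raster_cube(v, years, grid)
}

# Random valid index cube in [0, 100].
rand_cube <- function(nt, nr, nc, seed = 1L, lo = 0, hi = 100) {
  set.seed(seed)
  layers_cube(replicate(nt, matrix(runif(nr * nc, lo, hi), nr, nc),
                        simplify = FALSE))
}
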