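# small phantom configurations shared across tests

two_band_config <- function(seed, shape = c(120, 120, 120), contrast = 0.5,
                            speckle = 20) {
  phantom_config(
    shape_um = shape, depth_origin = 100,
    cell_layers = data.frame(
      depth_min = c(100, 100 + shape[3] / 2),
      depth_max = c(100 + shape[3] / 2, 100 + shape[3]),
      diameter_um = c(8, 13), diameter_sd = c(0.5, 0.8),
      density = c(80000, 40000)),
    contrast = contrast, speckle_shape = speckle, seed = seed)
}

two_band_bands <- function(shape = c(120, 120, 120)) {
  layer_bands(layer = c("II-IV", "V"),
              depth_min = c(100, 100 + shape[3] / 2),
              depth_max = c(100 + shape[3] / 2, 100 + shape[3]),
              kernel_um = c(8, 13), excluded = c(FALSE, FALSE))
}

single_cell_config <- function(diameter = 8, contrast = 0.5, shape = 40,
                               speckle = Inf, seed = 1) {
  phantom_config(
    shape_um = rep(shape, 3), depth_origin = 0,
    cell_layers = data.frame(depth_min = 0, depth_max = shape,
                             diameter_um = diameter, diameter_sd = 0,
                             n = 1),
    contrast = contrast, speckle_shape = speckle, seed = seed)
}

# uniformly scattered points as a minimal cell table
random_cells <- function(n, extent = c(200, 200, 200), seed = 1) {
  set.seed(seed)
  data.frame(x_um = runif(n, 0, extent[1]),
             y_um = runif(n, 0, extent[2]),
             z_um = runif(n, 0, extent[3]))
}

# brute-force NN oracle built on base dist()
nn_oracle <- function(pts) {
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  apply(d, 1, min)
}
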