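test_that("disk kernels have the expected footprint and unit sum", {
  k8 <- make_kernel("disk", 8, c(1, 1, 1))
  expect_lte(max(dim(k8)), 9)              # 8 um at 1 um pixels fits in 9x9
  expect_equal(sum(k8), 1)
  # 3-pixel diameter: the 5-pixel cross (offsets within radius (3-1)/2 = 1)
  k3 <- make_kernel("disk", 3, c(1, 1, 1))
  off <- attr(k3, "offsets")
  expect_equal(nrow(off), 5)
  expect_true(all(off$w == 0.2))
  expect_setequal(paste(off$dy, off$dx),
                  c("0 0", "1 0", "-1 0", "0 1", "0 -1"))
  expect_error(make_kernel("disk", 2, c(1, 1, 1)), "3 pixels")
})

test_that("orthogonal line kernels are transposes of each other", {
  k0 <- make_kernel("line", 9, c(1, 1, 1), orientation = 0)
  k90 <- make_kernel("line", 9, c(1, 1, 1), orientation = 90)
  expect_identical(t(unclass(k0)[, ]), unclass(k90)[, ], ignore_attr = TRUE)
  expect_equal(sum(k0), 1)
  expect_error(make_kernel("line", 2, c(1, 1, 1)), "3 pixels")
})

test_that("per-slice threshold marks exactly the top response pixels", {
  set.seed(11)
  n <- 100
  sl <- matrix(runif(n * n, 10, 20), n, n)
  vol <- oct_volume(array(sl, dim = c(n, n, 1)))
  kern <- make_kernel("disk", 8, c(1, 1, 1))
  cand <- detect_candidates(vol, kern, segmentation_params(), "dark")
  # oracle: brute-force convolution at reflective border + sort
  off <- attr(kern, "offsets")
  inv <- max(sl) - sl
  refl <- function(i, n) { while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i; if (i > n) i <- 2 * n + 1 - i }; i }
  resp <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (t in seq_len(nrow(off)))
      s <- s + off$w[t] * inv[refl(i + off$dy[t], n), refl(j + off$dx[t], n)]
    resp[i, j] <- s
  }
  thr <- quantile(resp, 0.995, names = FALSE)
  expect_identical(cand[, , 1], resp > thr)
  expect_equal(sum(cand), 50)  # 0.5% of 100x100, continuous values
})

test_that("the response peaks at a rendered cell center", {
  cfg <- single_cell_config(diameter = 8, contrast = 0.5, shape = 60,
                            speckle = 50, seed = 4)
  ph <- generate_phantom(cfg)
  truth <- ph$truth$cells
  kz <- round(truth$z) + 1
  sl <- ph$volume$data[, , kz]
  kern <- make_kernel("disk", 8, c(1, 1, 1))
  off <- attr(kern, "offsets")
  resp <- octcortex:::conv2_sparse(max(sl) - sl, off$dy, off$dx, off$w)
  pk <- arrayInd(which.max(resp), dim(resp))
  expect_lte(abs(pk[1] - 1 - truth$y), 1)
  expect_lte(abs(pk[2] - 1 - truth$x), 1)
})

test_that("constant slices produce no candidates, with a warning", {
  vol <- oct_volume(array(7, dim = c(30, 30, 1)))
  kern <- make_kernel("disk", 8, c(1, 1, 1))
  expect_warning(cand <- detect_candidates(vol, kern), "constant")
  expect_equal(sum(cand), 0)
})

test_that("disk kernels rank a cell above a filament under dark polarity", {
  arr <- array(100, dim = c(60, 60, 1))
  co <- seq_len(60) - 1
  d <- sqrt(outer((co - 20)^2, (co - 20)^2, "+"))
  arr[, , 1] <- arr[, , 1] * (1 - 0.5 * pmin(1, pmax(0, 4.5 - d)))  # dark cell
  arr[45, 10:50, 1] <- 180                                          # bright line
  kern <- make_kernel("disk", 8, c(1, 1, 1))
  off <- attr(kern, "offsets")
  sl <- arr[, , 1]
  resp <- octcortex:::conv2_sparse(max(sl) - sl, off$dy, off$dx, off$w)
  expect_gt(resp[21, 21], max(resp[45, 10:50]))
})

test_that("morphological conditions accept spheres and reject thin or long shapes", {
  # isolated 8 um sphere: exactly one accepted component, centroid <= 1 um off
  cfg <- single_cell_config(diameter = 8, contrast = 0.5, shape = 40)
  ph <- generate_phantom(cfg)
  kern <- make_kernel("disk", 8, c(1, 1, 1))
  suppressWarnings(cand <- detect_candidates(ph$volume, kern))
  m <- filter_components(cand, ph$volume, kernel_um = 8)
  expect_equal(nrow(m$cells), 1)
  truth <- ph$truth$cells
  err <- sqrt((m$cells$x_um - truth$x)^2 + (m$cells$y_um - truth$y)^2 +
                (m$cells$z_um - truth$z)^2)
  expect_lte(err, 1)

  vol <- oct_volume(array(1, dim = c(50, 50, 50)))
  blob2 <- array(FALSE, dim = c(50, 50, 50))
  blob2[20:26, 20:26, 10:11] <- TRUE   # spans only 2 axial slices
  m2 <- filter_components(blob2, vol, kernel_um = 8)
  expect_equal(nrow(m2$cells), 0)
  expect_equal(unname(m2$rejected["axial_min"]), 1L)

  tube <- array(FALSE, dim = c(50, 50, 50))
  d <- sqrt(outer((seq_len(50) - 25)^2, (seq_len(50) - 25)^2, "+"))
  for (k in 5:44) tube[, , k] <- d <= 4   # vessel proxy: 8 um wide, 40 um long
  m3 <- filter_components(tube, vol, kernel_um = 8)
  expect_equal(nrow(m3$cells), 0)
  expect_gte(unname(m3$rejected["axial_max"]), 1L)
})

test_that("layer-wise segmentation recovers both cell populations", {
  cfg <- two_band_config(7)
  ph <- generate_phantom(cfg)
  bands <- two_band_bands()
  m <- segment_cells(ph$volume, bands)
  ev <- evaluate_detection(m$cells, ph$truth$cells, match_radius_um = 5)
  expect_gte(ev$recall, 0.9)
  expect_gte(ev$ppv, 0.9)
  # both layers populated, roughly in proportion to seeding
  expect_setequal(unique(m$cells$layer), c("II-IV", "V"))
  n_truth <- table(ph$truth$cells$layer_row)
  n_seg <- table(m$cells$layer)[c("II-IV", "V")]
  expect_gt(min(as.numeric(n_seg) / as.numeric(n_truth)), 0.8)
})

test_that("an empty volume segments to an empty mask", {
  vol <- oct_volume(array(5, dim = c(40, 40, 30)), depth_origin = 100)
  bands <- layer_bands(layer = "II-IV", depth_min = 100, depth_max = 130,
                       kernel_um = 8, excluded = FALSE)
  suppressWarnings(m <- segment_cells(vol, bands))
  expect_equal(nrow(m$cells), 0)
  expect_true(all(m$labels == 0L))
})

test_that("a cell on a band boundary reports to the shallower band once", {
  expect_equal(assign_layer <- octcortex:::assign_layer(
    c(100, 250, 400, 50), layer_bands()),
    c("I", "II-IV", "II-IV", "I"))
  cfg <- phantom_config(
    shape_um = c(40, 40, 60), depth_origin = 0,
    cell_layers = data.frame(depth_min = 0, depth_max = 60, diameter_um = 8,
                             diameter_sd = 0, n = 1),
    speckle_shape = Inf, seed = 2)
  ph <- generate_phantom(cfg)
  ph$truth$cells$y <- 20; ph$truth$cells$x <- 20; ph$truth$cells$z <- 30
  vol <- octcortex:::render_phantom(ph$truth)
  bands <- layer_bands(layer = c("A", "B"), depth_min = c(0, 30),
                       depth_max = c(30, 60), kernel_um = c(8, 8),
                       excluded = c(FALSE, FALSE))
  suppressWarnings(m <- segment_cells(vol, bands))
  expect_equal(nrow(m$cells), 1)
  expect_equal(m$cells$layer, "A")
})

test_that("filament segmentation traces a bright tube and skips dark cells", {
  cfg <- phantom_config(
    shape_um = c(150, 150, 12), depth_origin = 0,
    cell_layers = data.frame(depth_min = 0, depth_max = 12, diameter_um = 8,
                             diameter_sd = 0, n = 1),
    filaments = data.frame(y = 110, x = 30, z = 6, length_um = 60,
                           theta_deg = 0, radius_um = 1),
    speckle_shape = 50, seed = 8)
  ph <- generate_phantom(cfg)
  fm <- segment_filaments(ph$volume, segmentation_params())
  # >= 80% of the centerline covered in the filament's own slice
  center_cov <- mean(fm[111, 31:90, 7])
  expect_gte(center_cov, 0.8)
  # the dark cell does not enter the bright-polarity mask
  tc <- ph$truth$cells
  cell_region <- fm[round(tc$y) + 0:2, round(tc$x) + 0:2, round(tc$z) + 1]
  expect_equal(sum(cell_region), 0)
})

test_that("rotating a slice by 90 degrees swaps the oriented responses", {
  set.seed(3)
  img <- matrix(runif(40 * 40), 40, 40)
  k0 <- attr(make_kernel("line", 9, c(1, 1, 1), 0), "offsets")
  k90 <- attr(make_kernel("line", 9, c(1, 1, 1), 90), "offsets")
  r0 <- octcortex:::conv2_sparse(img, k0$dy, k0$dx, k0$w)
  r90t <- octcortex:::conv2_sparse(t(img), k90$dy, k90$dx, k90$w)
  expect_equal(r0, t(r90t))
})

test_that("accepted voxels are a subset of candidates and records self-consistent", {
  cfg <- two_band_config(12, shape = c(100, 100, 60))
  cfg$cell_layers <- cfg$cell_layers[1, ]
  ph <- generate_phantom(cfg)
  kern <- make_kernel("disk", 8, c(1, 1, 1))
  cand <- detect_candidates(ph$volume, kern)
  m <- filter_components(cand, ph$volume, kernel_um = 8)
  expect_true(all(cand[m$labels > 0L]))
  # per-slice candidate fraction bounded by the threshold contract
  n_px <- prod(dim(ph$volume$data)[1:2])
  frac <- apply(cand, 3, mean)
  expect_true(all(frac <= 0.005 + 1 / n_px))
  # audit every record against its own voxels
  for (i in seq_len(nrow(m$cells))) {
    vox <- which(m$labels == m$cells$label[i])
    co <- arrayInd(vox, dim(m$labels))
    expect_equal(m$cells$n_voxels[i], length(vox))
    expect_equal(m$cells$volume_um3[i], length(vox))  # 1 um voxels
    expect_equal(m$cells$y_um[i], mean(co[, 1] - 1))
    expect_equal(m$cells$x_um[i], mean(co[, 2] - 1))
    expect_equal(m$cells$z_um[i],
                 ph$volume$depth_origin + mean(co[, 3] - 1))
    expect_equal(m$cells$axial_extent_um[i], diff(range(co[, 3])) + 1)
    a_max <- max(table(co[, 3]))
    expect_equal(m$cells$eq_diameter_um[i], 2 * sqrt(a_max / pi))
    # the acceptance conditions hold as stated
    expect_gte(m$cells$n_slices[i], 3)
    expect_gte(m$cells$axial_extent_um[i], 4)
    expect_lte(m$cells$volume_um3[i], (4 / 3) * pi * 4^3 + 1e-9)
    expect_lte(m$cells$axial_extent_um[i], 16 + 1e-9)
  }
})

test_that("whole-voxel shifts of the volume shift all centroids equally", {
  cfg <- two_band_config(21, shape = c(90, 90, 50))
  cfg$cell_layers <- cfg$cell_layers[1, ]
  ph <- generate_phantom(cfg)
  bands <- layer_bands("II-IV", 100, 150, 8, FALSE)
  m1 <- segment_cells(ph$volume, bands)
  d <- dim(ph$volume$data)
  shifted <- ph$volume$data[c((d[1] - 4):d[1], 1:(d[1] - 5)),
                            c((d[2] - 6):d[2], 1:(d[2] - 7)), ]
  m2 <- segment_cells(oct_volume(shifted, depth_origin = 100), bands)
  # compare interior cells only (circular wrap corrupts the borders)
  int1 <- m1$cells[m1$cells$y_um > 10 & m1$cells$y_um < d[1] - 16 &
                     m1$cells$x_um > 10 & m1$cells$x_um < d[2] - 18, ]
  p1 <- as_points(int1)
  p1[, 1] <- p1[, 1] + 7; p1[, 2] <- p1[, 2] + 5
  nn <- octcortex:::nn_brute(p1, as_points(m2$cells), FALSE)
  # the global per-slice threshold couples distant pixels through the
  # border reflection, so equivariance holds to a fraction of a voxel
  expect_lt(max(nn$dist), 0.5)
})

test_that("detection quality does not degrade as contrast rises", {
  seeds <- 1:5
  contrasts <- c(0.25, 0.5, 0.75)
  recall <- matrix(NA_real_, length(seeds), length(contrasts))
  ppv <- matrix(NA_real_, length(seeds), length(contrasts))
  for (s in seq_along(seeds)) {
    for (ci in seq_along(contrasts)) {
      cfg <- two_band_config(seeds[s], shape = c(80, 80, 40),
                             contrast = contrasts[ci])
      cfg$cell_layers <- cfg$cell_layers[1, ]
      ph <- generate_phantom(cfg)
      m <- segment_cells(ph$volume, layer_bands("II-IV", 100, 140, 8, FALSE))
      ev <- evaluate_detection(m$cells, ph$truth$cells, 5)
      recall[s, ci] <- ev$recall
      ppv[s, ci] <- if (is.na(ev$ppv)) 0 else ev$ppv
    }
  }
  # mean recall and PPV monotone (within small statistical slack)
  expect_true(all(diff(colMeans(recall)) > -0.05))
  expect_true(all(diff(colMeans(ppv)) > -0.05))
})
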