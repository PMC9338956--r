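random_rigid <- function(seed, max_deg = 5, max_trans = 20) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, -max_deg, max_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  rigid_transform(R, runif(3, -max_trans, max_trans))
}

test_that("rigid transforms compose, invert and validate", {
  a <- random_rigid(1); b <- random_rigid(2)
  p <- matrix(runif(30, 0, 100), 10, 3)
  expect_equal(apply_transform(compose_rigid(a, b), p),
               apply_transform(a, apply_transform(b, p)))
  expect_equal(apply_transform(compose_rigid(invert_rigid(a), a), p), p)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  # point extraction from cell tables
  cells <- data.frame(x_um = 1, y_um = 2, z_um = 3)
  expect_equal(as_points(cells), cbind(1, 2, 3))
})

test_that("coarse registration recovers constructed shifts and rotations", {
  cfg <- phantom_config(
    shape_um = c(160, 160, 60), depth_origin = 0,
    cell_layers = data.frame(depth_min = 0, depth_max = 60, diameter_um = 8,
                             diameter_sd = 0.5, n = 60),
    vessels = data.frame(axis = c("y", "x"), y = c(0, 100), x = c(60, 0),
                         z = c(30, 40), length_um = 160, radius_um = 5),
    seed = 11)
  ph <- generate_phantom(cfg)
  v <- ph$volume
  # identity
  tr0 <- coarse_register(v, v)
  expect_equal(tr0$translation, c(0, 0, 0))
  expect_equal(tr0$rotation, diag(3))
  # circular whole-pixel shift: moving(i, j) = fixed(i - 12, j + 7)
  d <- dim(v$data)
  sh <- v$data[c((d[1] - 11):d[1], 1:(d[1] - 12)),
               c(8:d[2], 1:7), , drop = FALSE]
  tr <- coarse_register(v, oct_volume(sh, v$spacing, v$depth_origin))
  expect_lte(max(abs(tr$translation - c(7, -12, 0))), 1)
  # rendered 4-degree in-plane rotation (vessels carry the motion)
  pair <- make_session_pair(cfg, rigid = rigid_z_rotation(4, c(12, -7, 0)))
  tr2 <- coarse_register(pair$volume_t1, pair$volume_t0)
  expect_lte(abs(octcortex:::rotation_angle_deg(tr2$rotation) - 4), 0.5)
  expect_lte(max(abs(tr2$translation[1:2] - c(12, -7))), 2)
  # non-overlapping inputs are refused
  set.seed(1)
  noise <- oct_volume(array(runif(length(v$data)), d))
  expect_error(coarse_register(v, noise), "coarse registration failed")
})

test_that("rigid ICP recovers known transforms and is gate-robust", {
  set.seed(20)
  fixed <- matrix(runif(600, 0, 200), 200, 3)
  truth <- rigid_z_rotation(3, c(5, 0, 0))
  # moving points such that truth maps moving onto fixed
  moving <- apply_transform(invert_rigid(truth), fixed)
  est <- icp_rigid(fixed, moving, gate_um = 10)
  expect_lte(abs(octcortex:::rotation_angle_deg(est$rotation) - 3), 0.1)
  expect_lte(max(abs(est$translation - truth$translation)), 0.1)

  # identical sets: identity at once
  est0 <- icp_rigid(fixed, fixed)
  expect_equal(est0$rotation, diag(3), tolerance = 1e-8)
  expect_lte(max(abs(est0$translation)), 1e-6)

  # 20% outliers far beyond the gate leave the estimate unchanged
  out <- matrix(runif(120, 400, 800), 40, 3)
  est2 <- icp_rigid(fixed, rbind(moving, out), gate_um = 10)
  expect_lte(max(abs(est2$translation - truth$translation)), 0.5)
  expect_lte(abs(octcortex:::rotation_angle_deg(est2$rotation) - 3), 0.2)

  # gated mean distance never increases across iterations
  jit <- moving + matrix(rnorm(600, 0, 1), 200, 3)
  est3 <- icp_rigid(fixed, jit, gate_um = 10)
  expect_true(all(diff(attr(est3, "trace")) <= 1e-12))

  expect_error(icp_rigid(fixed[1:2, ], moving[1:2, ]), "3 points")
  expect_error(icp_rigid(fixed, moving + 500, gate_um = 10), "diverged")
})

test_that("elastic registration reduces to rigid on purely rigid motion", {
  set.seed(4)
  fixed <- matrix(runif(3 * 900, 0, 150), ncol = 3)
  rig <- rigid_z_rotation(2, c(4, -3, 1))
  moving <- apply_transform(invert_rigid(rig), fixed)
  field <- elastic_register(fixed, moving, rig)
  expect_true(any(field$blocks$own))
  p <- matrix(runif(60, 20, 130), 20, 3)
  expect_equal(evaluate_field(field, p), apply_transform(rig, p),
               tolerance = 1e-4)
})

test_that("sparse blocks inherit the rigid transform verbatim", {
  set.seed(5)
  # 6 cells in each 50 um block: below the >10 threshold everywhere
  corners <- as.matrix(expand.grid(c(0, 50), c(0, 50), c(0, 50)))
  fixed <- do.call(rbind, lapply(seq_len(nrow(corners)), function(i)
    sweep(matrix(runif(18, 5, 45), 6, 3), 2, corners[i, ], "+")))
  rig <- rigid_transform(translation = c(2, 0, 0))
  moving <- apply_transform(invert_rigid(rig), fixed)
  expect_warning(field <- elastic_register(fixed, moving, rig), "rigid-only")
  expect_true(all(!field$blocks$own))
  expect_true(all(field$blocks$ux == 0 & field$blocks$uy == 0 &
                    field$blocks$uz == 0))
  p <- matrix(runif(30, 0, 100), 10, 3)
  expect_equal(evaluate_field(field, p), apply_transform(rig, p))
})

test_that("a quadratic deformation field is recovered within 1 um RMS", {
  set.seed(6)
  n <- 4000
  L <- 250
  moving <- matrix(runif(3 * n, 0, L), ncol = 3)
  coef <- matrix(0, 3, 10)
  coef[1, 5] <- 4 / L^2      # u_x = 4 um * (x/L)^2
  coef[2, 4] <- 2 / L        # u_y = 2 um * z/L
  truthfield <- quadratic_field(coef)
  rig <- rigid_z_rotation(1, c(3, 2, -1))
  fixed <- apply_transform(rig, moving + truthfield(moving))
  est_rigid <- icp_rigid(fixed, moving, gate_um = 10)
  field <- elastic_register(fixed, moving, est_rigid)
  pred <- evaluate_field(field, moving)
  rms <- sqrt(mean(rowSums((pred - fixed)^2)))
  expect_lte(rms, 1)
  # elasticity map deltas match the analytic elastic-minus-rigid offsets
  em <- elasticity_map(moving, est_rigid, field)
  truth_delta <- fixed - apply_transform(est_rigid, moving)
  got_delta <- cbind(em$dx_um, em$dy_um, em$dz_um)
  expect_lte(sqrt(mean(rowSums((got_delta - truth_delta)^2))), 1)
})

test_that("elasticity deltas survive a change of coordinate frame", {
  set.seed(8)
  n <- 2500
  moving <- matrix(runif(3 * n, 0, 200), ncol = 3)
  coef <- matrix(0, 3, 10); coef[1, 5] <- 3 / 200^2
  fixed <- moving + quadratic_field(coef)(moving)
  rig <- icp_rigid(fixed, moving, gate_um = 10)
  em1 <- elasticity_map(moving, rig,
                        elastic_register(fixed, moving, rig))
  shift <- c(40, -30, 25)
  mv2 <- sweep(moving, 2, shift, "+")
  fx2 <- sweep(fixed, 2, shift, "+")
  rig2 <- icp_rigid(fx2, mv2, gate_um = 10)
  em2 <- elasticity_map(mv2, rig2, elastic_register(fx2, mv2, rig2))
  expect_equal(cbind(em2$dx_um, em2$dy_um, em2$dz_um),
               cbind(em1$dx_um, em1$dy_um, em1$dz_um), tolerance = 0.05)
})

test_that("cell matching is one-to-one, gated and symmetric", {
  set.seed(9)
  fixed <- matrix(runif(3 * 300, 0, 200), ncol = 3)
  # identical sets under identity: full match at distance zero
  ms <- match_cells(fixed, fixed, rigid_transform())
  expect_equal(attr(ms, "matched_fraction"), 1)
  expect_true(all(ms$dist_um == 0))
  expect_equal(anyDuplicated(ms$fixed), 0)
  expect_equal(anyDuplicated(ms$moving), 0)

  # deleting half the moving cells halves the matched fraction
  half <- fixed[1:150, ]
  ms2 <- match_cells(fixed, half, rigid_transform())
  expect_lte(abs(attr(ms2, "matched_fraction") - 0.5), 1 / 300)

  # two fixed cells 4 um apart, one moving point between: exactly one match
  f3 <- rbind(c(0, 0, 0), c(4, 0, 0))
  m3 <- matrix(c(2.4, 0, 0), 1)
  ms3 <- match_cells(f3, m3, rigid_transform())
  expect_equal(nrow(ms3), 1)

  # all match distances below the gate
  jit <- fixed + matrix(rnorm(900, 0, 2), ncol = 3)
  ms4 <- match_cells(fixed, jit, rigid_transform(), gate_um = 10)
  expect_true(all(ms4$dist_um < 10))
  # role swap changes the matched fraction by at most 2 points
  ms5 <- match_cells(jit, fixed, rigid_transform(), gate_um = 10)
  expect_lte(abs(attr(ms4, "matched_fraction") -
                   attr(ms5, "matched_fraction")), 0.02)

  # empty input
  ms6 <- match_cells(fixed[0, ], fixed, rigid_transform())
  expect_equal(nrow(ms6), 0)
  expect_equal(attr(ms6, "matched_fraction"), 0)
})

test_that("displacement histograms localize the per-axis offsets", {
  # well-separated grid so matching is unambiguous under small offsets
  g <- as.matrix(expand.grid(seq(0, 120, 15), seq(0, 120, 15),
                             seq(0, 60, 20)))
  f <- g[1:300, ]
  ms <- match_cells(f, f, rigid_transform())
  h <- displacement_histograms(ms)
  centre <- function(hh) hh$fraction[hh$mid == 0.25 | hh$mid == -0.25]
  expect_equal(sum(centre(h$x)), 1)
  expect_equal(sum(centre(h$y)), 1)
  expect_equal(sum(centre(h$z)), 1)

  # a pure +2.2 um x-residual lands in its own bin, y and z stay central
  ms_shift <- match_cells(f, sweep(f, 2, c(2.2, 0, 0), "-"),
                          rigid_transform())
  h2 <- displacement_histograms(ms_shift)
  expect_equal(h2$x$fraction[h2$x$mid == 2.25], 1)
  expect_equal(sum(centre(h2$y)), 1)

  # gaussian jitter: sample SD of binned offsets within 15% of the truth
  set.seed(10)
  jit <- f + matrix(rnorm(900, 0, 1), 300, 3)
  h3 <- displacement_histograms(match_cells(f, jit, rigid_transform()))
  sd_x <- sqrt(sum(h3$x$fraction * h3$x$mid^2) -
                 sum(h3$x$fraction * h3$x$mid)^2)
  expect_lt(abs(sd_x - 1), 0.15)
})
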