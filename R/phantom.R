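#' Configure a synthetic cortical OCT phantom
#'
#' The phantom emulates the appearance of label-free OCT of cortex: cell
#' bodies as quasi-spherical dark foci, myelinated axons as bright in-plane
#' filaments, blood vessels as dark tubes, all under multiplicative
#' fully-developed speckle (unit-mean gamma). Geometry is recorded exactly
#' as ground truth, so detector performance (PPV, recall, centroid error)
#' is well defined.
#'
#' @param shape_um volume extent `c(y, x, z)` in um.
#' @param spacing `c(dz, dy, dx)` um/voxel.
#' @param depth_origin depth of the first slice, um.
#' @param cell_layers data frame with one row per depth band of cells:
#'   columns `depth_min`, `depth_max` (um), `diameter_um` (mean),
#'   `diameter_sd` (um), and either `n` (count) or `density` (cells/mm^3).
#' @param contrast fractional intensity dip at a cell center, in `(0, 1]`.
#' @param min_sep_factor minimum center separation between cells as a
#'   multiple of the mean diameter (rejection sampling).
#' @param vessels data frame of axis-aligned tubes: columns `axis`
#'   (`"z"`, `"y"` or `"x"`), `y`, `x`, `z` (um; the coordinate along
#'   `axis` gives the tube start), `length_um`, `radius_um`. `NULL` for none.
#' @param vessel_contrast fractional dip inside vessels.
#' @param filaments number of bright in-plane filaments, or a data frame
#'   with columns `y`, `x`, `z`, `length_um`, `theta_deg` (en-face
#'   orientation), `radius_um`.
#' @param filament_gain fractional brightness gain at a filament core.
#' @param background mean background intensity (arbitrary units).
#' @param speckle_shape shape parameter of the unit-mean gamma speckle
#'   (larger = smoother); `Inf` disables speckle.
#' @param seed integer seed making the phantom fully reproducible.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape_um = c(200, 200, 160),
                           spacing = c(1, 1, 1),
                           depth_origin = 100,
                           cell_layers = data.frame(
                             depth_min = c(100, 190),
                             depth_max = c(190, 260),
                             diameter_um = c(8, 13),
                             diameter_sd = c(0.5, 0.8),
                             density = c(80000, 40000)),
                           contrast = 0.5,
                           min_sep_factor = 1.5,
                           vessels = NULL,
                           vessel_contrast = 0.5,
                           filaments = 0,
                           filament_gain = 0.8,
                           background = 100,
                           speckle_shape = 20,
                           seed = 1L) {
  stopifnot(contrast > 0, contrast <= 1, background > 0,
            is.finite(speckle_shape) || is.infinite(speckle_shape))
  if (!is.null(cell_layers) && nrow(cell_layers) > 0) {
    if (any(cell_layers$diameter_um <= 2 * max(spacing)))
      stop("cell diameters must exceed 2 x max voxel spacing")
    if (!is.null(cell_layers$density) && any(cell_layers$density < 0))
      stop("densities must be >= 0")
  }
  structure(list(
    shape_um = shape_um, spacing = as.numeric(spacing),
    depth_origin = depth_origin, cell_layers = cell_layers,
    contrast = contrast, min_sep_factor = min_sep_factor,
    vessels = vessels, vessel_contrast = vessel_contrast,
    filaments = filaments, filament_gain = filament_gain,
    background = background, speckle_shape = speckle_shape,
    seed = as.integer(seed)), class = "phantom_config")
}

# place cell centers by rejection sampling with a minimum separation
place_cells <- function(config) {
  cl <- config$cell_layers
  if (is.null(cl) || nrow(cl) == 0)
    return(data.frame(y = numeric(0), x = numeric(0), z = numeric(0),
                      radius_um = numeric(0), layer_row = integer(0)))
  sy <- config$shape_um[1]; sx <- config$shape_um[2]
  out <- vector("list", nrow(cl))
  placed <- matrix(numeric(0), 0, 3)
  placed_r <- numeric(0)
  for (i in seq_len(nrow(cl))) {
    zmin <- cl$depth_min[i]; zmax <- cl$depth_max[i]
    dmean <- cl$diameter_um[i]; dsd <- cl$diameter_sd[i]
    n <- if (!is.null(cl$n) && !is.na(cl$n[i])) cl$n[i] else {
      vol_mm3 <- sy * sx * (zmax - zmin) * 1e-9
      round((if (is.null(cl$density)) 0 else cl$density[i]) * vol_mm3)
    }
    min_sep <- config$min_sep_factor * dmean
    margin <- dmean / 2 + 2
    pts <- matrix(NA_real_, n, 3)
    rad <- numeric(n)
    got <- 0L; tries <- 0L
    while (got < n) {
      tries <- tries + 1L
      if (tries > 200L * n + 1000L)
        stop("cells denser than packable at min separation ",
             min_sep, " um (placed ", got, " of ", n, ")")
      p <- c(stats::runif(1, margin, sy - margin),
             stats::runif(1, margin, sx - margin),
             stats::runif(1, zmin + margin, zmax - margin))
      all_pts <- rbind(placed, if (got > 0) pts[seq_len(got), , drop = FALSE])
      if (nrow(all_pts) > 0) {
        d2 <- (all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2 +
          (all_pts[, 3] - p[3])^2
        if (min(d2) < min_sep^2) next
      }
      got <- got + 1L
      pts[got, ] <- p
      rad[got] <- pmax(2 * max(config$spacing),
                       stats::rnorm(1, dmean, dsd)) / 2
    }
    out[[i]] <- data.frame(y = pts[, 1], x = pts[, 2], z = pts[, 3],
                           radius_um = rad, layer_row = i)
    placed <- rbind(placed, pts)
    placed_r <- c(placed_r, rad)
  }
  do.call(rbind, out)
}

# default filament geometry: random in-plane segments at the 4 canonical
# orientations
place_filaments <- function(config) {
  f <- config$filaments
  if (is.data.frame(f)) return(f)
  n <- as.integer(f)
  if (n == 0)
    return(data.frame(y = numeric(0), x = numeric(0), z = numeric(0),
                      length_um = numeric(0), theta_deg = numeric(0),
                      radius_um = numeric(0)))
  sy <- config$shape_um[1]; sx <- config$shape_um[2]
  zlo <- config$depth_origin; zhi <- config$depth_origin + config$shape_um[3]
  data.frame(
    y = stats::runif(n, 0.2 * sy, 0.8 * sy),
    x = stats::runif(n, 0.2 * sx, 0.8 * sx),
    z = stats::runif(n, zlo + 5, zhi - 5),
    length_um = stats::runif(n, 30, 60),
    theta_deg = sample(c(0, 45, 90, 135), n, replace = TRUE),
    radius_um = 1)
}

# anti-aliased coverage: 1 inside, 0 outside, linear ramp of one voxel
# across the boundary (partial-volume approximation)
aa_coverage <- function(dist, radius, edge = 1) {
  pmin(1, pmax(0, (radius + edge / 2 - dist) / edge))
}

# voxel center coordinates along each axis, um
axis_coords <- function(config) {
  dims <- phantom_dims(config)
  list(y = (seq_len(dims[1]) - 1) * config$spacing[2],
       x = (seq_len(dims[2]) - 1) * config$spacing[3],
       z = config$depth_origin + (seq_len(dims[3]) - 1) * config$spacing[1])
}

phantom_dims <- function(config) {
  c(ceiling(config$shape_um[1] / config$spacing[2]),
    ceiling(config$shape_um[2] / config$spacing[3]),
    ceiling(config$shape_um[3] / config$spacing[1]))
}

# multiplicative patch of a ball over its bounding box; the caller applies
# it in place (passing the big array through a function would copy it)
ball_patch <- function(co, center, radius, mult) {
  iy <- which(abs(co$y - center[1]) <= radius + 1.5)
  ix <- which(abs(co$x - center[2]) <= radius + 1.5)
  iz <- which(abs(co$z - center[3]) <= radius + 1.5)
  if (!length(iy) || !length(ix) || !length(iz)) return(NULL)
  dy2 <- (co$y[iy] - center[1])^2
  dx2 <- (co$x[ix] - center[2])^2
  dz2 <- (co$z[iz] - center[3])^2
  d <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))
  list(iy = iy, ix = ix, iz = iz,
       factor = 1 + mult * aa_coverage(d, radius))
}

# multiplicative patch of a tube along an arbitrary unit direction
tube_patch <- function(co, p0, dir, length_um, radius, mult) {
  dir <- dir / sqrt(sum(dir^2))
  p1 <- p0 + dir * length_um
  lo <- pmin(p0, p1) - radius - 1.5
  hi <- pmax(p0, p1) + radius + 1.5
  iy <- which(co$y >= lo[1] & co$y <= hi[1])
  ix <- which(co$x >= lo[2] & co$x <= hi[2])
  iz <- which(co$z >= lo[3] & co$z <= hi[3])
  if (!length(iy) || !length(ix) || !length(iz)) return(NULL)
  g <- expand.grid(y = co$y[iy], x = co$x[ix], z = co$z[iz])
  rel <- cbind(g$y - p0[1], g$x - p0[2], g$z - p0[3])
  t <- pmin(pmax(rel %*% dir, 0), length_um)
  perp <- rel - t %*% t(dir)
  d <- sqrt(rowSums(perp^2))
  list(iy = iy, ix = ix, iz = iz,
       factor = array(1 + mult * aa_coverage(d, radius),
                      dim = c(length(iy), length(ix), length(iz))))
}

#' Generate a synthetic cortical OCT phantom
#'
#' Renders cells (multiplicative dark spheres), vessels (dark tubes) and
#' filaments (bright tubes) onto a constant background, applies unit-mean
#' gamma speckle, and returns both the volume and its exact ground truth.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return A list of class `phantom` with elements `volume`
#'   ([oct_volume()]) and `truth` (list: `cells` data frame with centers in
#'   um and radii, `vessels`, `filaments`, and the `config`).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  cells <- place_cells(config)
  fils <- place_filaments(config)
  truth <- list(cells = cells, vessels = config$vessels, filaments = fils,
                config = config)
  vol <- render_phantom(truth)
  list(volume = vol, truth = truth)
}

# render a volume from a truth record (used for both sessions of a pair;
# speckle is drawn from the current RNG state)
render_phantom <- function(truth) {
  config <- truth$config
  dims <- phantom_dims(config)
  co <- axis_coords(config)
  arr <- array(1, dim = dims)
  # patches are applied inline: subassignment stays copy-free only while
  # `arr` has a single reference in this frame
  cells <- truth$cells
  if (!is.null(cells) && nrow(cells) > 0) {
    for (i in seq_len(nrow(cells))) {
      p <- ball_patch(co, c(cells$y[i], cells$x[i], cells$z[i]),
                      cells$radius_um[i], -config$contrast)
      if (!is.null(p))
        arr[p$iy, p$ix, p$iz] <- arr[p$iy, p$ix, p$iz] * p$factor
    }
  }
  ves <- truth$vessels
  if (!is.null(ves) && nrow(ves) > 0) {
    for (i in seq_len(nrow(ves))) {
      dir <- if (!is.null(ves$axis)) {
        switch(ves$axis[i], z = c(0, 0, 1), y = c(1, 0, 0), x = c(0, 1, 0),
               stop("vessel axis must be one of z, y, x"))
      } else c(ves$dir_y[i], ves$dir_x[i], ves$dir_z[i])
      p <- tube_patch(co, c(ves$y[i], ves$x[i], ves$z[i]), dir,
                      ves$length_um[i], ves$radius_um[i],
                      -config$vessel_contrast)
      if (!is.null(p))
        arr[p$iy, p$ix, p$iz] <- arr[p$iy, p$ix, p$iz] * p$factor
    }
  }
  fils <- truth$filaments
  if (!is.null(fils) && nrow(fils) > 0) {
    for (i in seq_len(nrow(fils))) {
      th <- fils$theta_deg[i] * pi / 180
      dir <- c(sin(th), cos(th), 0)  # in-plane
      p <- tube_patch(co, c(fils$y[i], fils$x[i], fils$z[i]), dir,
                      fils$length_um[i], fils$radius_um[i],
                      config$filament_gain)
      if (!is.null(p))
        arr[p$iy, p$ix, p$iz] <- arr[p$iy, p$ix, p$iz] * p$factor
    }
  }
  arr <- arr * config$background
  if (is.finite(config$speckle_shape)) {
    k <- config$speckle_shape
    arr <- arr * array(stats::rgamma(length(arr), shape = k, rate = k),
                       dim = dims)
  }
  oct_volume(arr, spacing = config$spacing, depth_origin = config$depth_origin)
}

#' Analytic quadratic displacement field
#'
#' A smooth per-axis displacement used to emulate slow tissue deformation
#' between imaging sessions. Each component is a second-order polynomial of
#' position `p = (x, y, z)` um:
#' `u_j(p) = c0 + cx x + cy y + cz z + cxx x^2 + cyy y^2 + czz z^2 +
#'  cxy xy + cxz xz + cyz yz`.
#'
#' @param coef 3 x 10 numeric matrix; rows = displacement components
#'   (x, y, z), columns = terms
#'   `1, x, y, z, x2, y2, z2, xy, xz, yz`. Defaults to zero.
#' @return A function `f(points)` mapping an `n x 3` matrix (columns
#'   x, y, z um) to an `n x 3` displacement matrix, with the coefficient
#'   matrix attached as attribute `coef`.
#' @export
quadratic_field <- function(coef = matrix(0, 3, 10)) {
  coef <- as.matrix(coef)
  stopifnot(nrow(coef) == 3, ncol(coef) == 10)
  f <- function(points) {
    points <- as_points(points)
    X <- quad_basis(points)
    X %*% t(coef)
  }
  attr(f, "coef") <- coef
  f
}

quad_basis <- function(p) {
  cbind(1, p[, 1], p[, 2], p[, 3], p[, 1]^2, p[, 2]^2, p[, 3]^2,
        p[, 1] * p[, 2], p[, 1] * p[, 3], p[, 2] * p[, 3])
}

# rigidly move axis-aligned vessels: start point transformed, direction
# rotated; output uses generic direction columns
transform_vessels <- function(ves, rigid) {
  if (is.null(ves) || nrow(ves) == 0) return(ves)
  dirs <- t(vapply(ves$axis, function(ax)
    switch(ax, z = c(0, 0, 1), y = c(1, 0, 0), x = c(0, 1, 0)), numeric(3)))
  # columns of dirs are (y, x, z); transform works in (x, y, z)
  p0 <- cbind(ves$x, ves$y, ves$z)
  p0t <- apply_transform(rigid, p0)
  d_xyz <- cbind(dirs[, 2], dirs[, 1], dirs[, 3]) %*% t(rigid$rotation)
  data.frame(y = p0t[, 2], x = p0t[, 1], z = p0t[, 3],
             dir_y = d_xyz[, 2], dir_x = d_xyz[, 1], dir_z = d_xyz[, 3],
             length_um = ves$length_um, radius_um = ves$radius_um)
}

transform_filaments <- function(fils, rigid) {
  if (is.null(fils) || nrow(fils) == 0) return(fils)
  p0t <- apply_transform(rigid, cbind(fils$x, fils$y, fils$z))
  phi <- atan2(rigid$rotation[2, 1], rigid$rotation[1, 1]) * 180 / pi
  out <- fils
  out$x <- p0t[, 1]; out$y <- p0t[, 2]; out$z <- p0t[, 3]
  out$theta_deg <- fils$theta_deg + phi
  out
}

#' Generate a longitudinal phantom session pair
#'
#' Session 1 is a fresh phantom; session 2 re-renders the same cells after
#' moving every center by `rigid(p + elastic(p))` — a known rigid motion
#' composed with a smooth analytic deformation — with an independent
#' speckle realization. The applied motion is recorded in the truth so
#' registration accuracy can be scored exactly.
#'
#' @param config a [phantom_config()].
#' @param rigid a [rigid_transform()] (identity by default).
#' @param elastic a displacement function as from [quadratic_field()], or
#'   `NULL` for none. Its maximum magnitude over the cells must stay below
#'   half the minimum cell separation, else correspondence is ambiguous.
#' @return List of class `phantom_pair`: `volume_t0`, `volume_t1`, `truth`
#'   (cells of both sessions, the rigid transform and elastic function).
#' @export
make_session_pair <- function(config, rigid = rigid_transform(),
                              elastic = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  cells0 <- place_cells(config)
  fils <- place_filaments(config)
  p0 <- cbind(x = cells0$x, y = cells0$y, z = cells0$z)
  u <- if (is.null(elastic)) matrix(0, nrow(p0), 3) else elastic(p0)
  if (nrow(p0) > 1) {
    min_sep <- min(nn_brute(cbind(p0[, 1], p0[, 2], p0[, 3]), p0, TRUE)$dist)
    if (max(sqrt(rowSums(u^2))) > min_sep / 2)
      stop("elastic displacement exceeds half the minimum cell separation")
  }
  p1 <- apply_transform(rigid, p0 + u)
  cells1 <- cells0
  cells1$x <- p1[, 1]; cells1$y <- p1[, 2]; cells1$z <- p1[, 3]
  truth0 <- list(cells = cells0, vessels = config$vessels, filaments = fils,
                 config = config)
  # vessels and filaments follow the rigid motion (they anchor coarse
  # vessel-based registration); the small elastic field moves cells only
  truth1 <- list(cells = cells1,
                 vessels = transform_vessels(config$vessels, rigid),
                 filaments = transform_filaments(fils, rigid),
                 config = config)
  v0 <- render_phantom(truth0)
  v1 <- render_phantom(truth1)
  structure(list(
    volume_t0 = v0, volume_t1 = v1,
    truth = list(cells_t0 = cells0, cells_t1 = cells1, rigid = rigid,
                 elastic = elastic, config = config)),
    class = "phantom_pair")
}
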