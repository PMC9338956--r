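#' Rigid 3D transform
#'
#' Rotation plus translation in physical (um) coordinates; applied to
#' points as `p' = R p + t` with points as rows `(x, y, z)`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector, um.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf(
    "<rigid_transform> rotation %.3f deg, translation (%.2f, %.2f, %.2f) um\n",
    ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation about the optical (z) axis
#' @param theta_deg in-plane rotation angle, degrees (counter-clockwise in
#'   the x-y plane).
#' @param translation length-3 translation, um.
#' @return A [rigid_transform()].
#' @export
rigid_z_rotation <- function(theta_deg, translation = c(0, 0, 0)) {
  th <- theta_deg * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0),
             c(sin(th),  cos(th), 0),
             c(0, 0, 1))
  rigid_transform(R, translation)
}

#' Apply a rigid transform or displacement field to points
#' @param transform a [rigid_transform()] or `displacement_field`.
#' @param points `n x 3` matrix (columns x, y, z um) or a cell table with
#'   `x_um`, `y_um`, `z_um` columns.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(transform, points) {
  points <- as_points(points)
  if (inherits(transform, "displacement_field"))
    return(evaluate_field(transform, points))
  p <- points %*% t(transform$rotation)
  sweep(p, 2, transform$translation, "+")
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()]s.
#' @return the rigid transform `p -> a(b(p))`.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return its inverse.
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Extract point coordinates from a cell table or matrix
#' @param x cell table (with `x_um`, `y_um`, `z_um`) or `n x 3` matrix.
#' @return `n x 3` numeric matrix, columns x, y, z (um).
#' @export
as_points <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    return(unname(x))
  }
  if (is.data.frame(x) && all(c("x_um", "y_um", "z_um") %in% names(x)))
    return(unname(cbind(x$x_um, x$y_um, x$z_um)))
  if (is.data.frame(x) && all(c("x", "y", "z") %in% names(x)))
    return(unname(cbind(x$x, x$y, x$z)))
  stop("cannot interpret `x` as 3D points")
}

# mean-intensity en-face projection as a matrix (y, x)
enface_projection <- function(vol) {
  d <- dim(vol$data)
  matrix(rowMeans(matrix(vol$data, d[1] * d[2], d[3])), d[1], d[2])
}

# integer-pixel translation (dy, dx) of `mov` onto `fix` by FFT
# cross-correlation of mean-subtracted images; returns shift and the
# normalized correlation score at the peak
xcorr_shift <- function(fix, mov) {
  nr <- nrow(fix); nc <- ncol(fix)
  pr <- 2 * nr; pc <- 2 * nc
  A <- matrix(0, pr, pc); B <- matrix(0, pr, pc)
  A[1:nr, 1:nc] <- fix - mean(fix)
  B[1:nr, 1:nc] <- mov - mean(mov)
  cc <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)),
                      inverse = TRUE)) / (pr * pc)
  pk <- which.max(cc)
  ij <- arrayInd(pk, c(pr, pc))
  dy <- ij[1] - 1; dx <- ij[2] - 1
  if (dy > pr / 2) dy <- dy - pr
  if (dx > pc / 2) dx <- dx - pc
  score <- max(cc) / (sqrt(sum(A^2) * sum(B^2)) + 1e-12)
  list(dy = dy, dx = dx, score = score)
}

# rotate an image about its center by theta_deg (bilinear)
rotate_image <- function(img, theta_deg, fill = 0) {
  if (theta_deg == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- theta_deg * pi / 180
  g <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  # inverse map: source = R(-theta) (target - c) + c
  ys <- cos(th) * (g$i - cy) + sin(th) * (g$j - cx) + cy
  xs <- -sin(th) * (g$i - cy) + cos(th) * (g$j - cx) + cx
  i0 <- floor(ys); j0 <- floor(xs)
  fy <- ys - i0; fx <- xs - j0
  val <- rep(fill, nrow(g))
  ok <- i0 >= 1 & i0 < nr & j0 >= 1 & j0 < nc
  idx <- function(i, j) (j - 1) * nr + i
  v <- img
  val[ok] <- (1 - fy[ok]) * (1 - fx[ok]) * v[idx(i0[ok], j0[ok])] +
    (1 - fy[ok]) * fx[ok] * v[idx(i0[ok], j0[ok] + 1)] +
    fy[ok] * (1 - fx[ok]) * v[idx(i0[ok] + 1, j0[ok])] +
    fy[ok] * fx[ok] * v[idx(i0[ok] + 1, j0[ok] + 1)]
  matrix(val, nr, nc)
}

#' Coarse vessel-based en-face registration
#'
#' Estimates the in-plane motion between two sessions from their
#' mean-intensity en-face projections, in which blood vessels are the
#' dominant dark structures: translation by the FFT cross-correlation
#' peak, in-plane rotation by exhaustive search (default +/- 10 degrees
#' at 0.5 degree steps) maximizing the correlation score. Out-of-plane
#' components are zero; depth alignment is left to the rigid ICP stage.
#'
#' @param fixed,moving [oct_volume()]s of the same field of view.
#' @param max_rotation_deg,rotation_step_deg rotation search range/step.
#' @param min_score minimum normalized correlation at the peak; below it
#'   the volumes are declared non-overlapping and an error is raised.
#' @return A [rigid_transform()] mapping moving to fixed (z untouched).
#' @export
coarse_register <- function(fixed, moving, max_rotation_deg = 10,
                            rotation_step_deg = 0.5, min_score = 0.05) {
  stopifnot(inherits(fixed, "oct_volume"), inherits(moving, "oct_volume"))
  fp <- enface_projection(fixed)
  mp <- enface_projection(moving)
  fp <- fp - mean(fp)
  mp <- mp - mean(mp)  # rotation fill (0) is then intensity-neutral
  angles <- seq(-max_rotation_deg, max_rotation_deg, by = rotation_step_deg)
  best <- list(score = -Inf)
  for (a in angles) {
    rm <- rotate_image(mp, a)
    s <- xcorr_shift(fp, rm)
    if (s$score > best$score) best <- list(score = s$score, angle = a,
                                           dy = s$dy, dx = s$dx)
  }
  if (best$score < min_score)
    stop("coarse registration failed: correlation peak ", signif(best$score, 3),
         " below floor (insufficient overlap)")
  sp <- fixed$spacing
  # rotation about the lateral center, then translation; express globally
  d <- dim(moving$data)
  center <- c(((d[2] + 1) / 2 - 1) * sp["x"], ((d[1] + 1) / 2 - 1) * sp["y"], 0)
  # rotate_image(theta) turns content by -theta in physical (x, y) coords
  rot <- rigid_z_rotation(-best$angle)
  t_shift <- c(best$dx * sp["x"], best$dy * sp["y"], 0)
  tr <- center - as.numeric(rot$rotation %*% center) + t_shift
  out <- rigid_transform(rot$rotation, tr)
  attr(out, "score") <- best$score
  out
}

#' Rigid ICP on cell centroids
#'
#' Iterative closest point with a hard correspondence gate: each moving
#' point matches its nearest fixed point if within `gate_um`; the rigid
#' transform over the gated matches is solved in closed form (orthogonal
#' Procrustes / Kabsch) and re-applied until the mean gated match
#' distance improves by less than `tol_um` or `max_iter` is reached.
#'
#' @param fixed_pts,moving_pts point sets (`n x 3` matrices or cell
#'   tables); at least 3 non-collinear points each.
#' @param gate_um correspondence gate, um (default 10: registered cells
#'   are assumed less than 10 um apart).
#' @param init initial [rigid_transform()] (e.g. from
#'   [coarse_register()]).
#' @param tol_um convergence tolerance on the mean match distance.
#' @param max_iter iteration cap.
#' @return A [rigid_transform()] mapping moving to fixed, with attributes
#'   `trace` (mean gated distance per iteration, non-increasing) and
#'   `n_matches`.
#' @export
icp_rigid <- function(fixed_pts, moving_pts, gate_um = 10,
                      init = rigid_transform(), tol_um = 1e-3,
                      max_iter = 50L) {
  f <- as_points(fixed_pts)
  m <- as_points(moving_pts)
  if (nrow(f) < 3 || nrow(m) < 3) stop("ICP needs at least 3 points per set")
  current <- init
  trace <- numeric(0)
  n_matches <- 0L
  gated_mean <- function(tr) {
    nn <- nn_brute(apply_transform(tr, m), f, FALSE)
    gated <- which(nn$dist < gate_um)
    list(nn = nn, gated = gated,
         mean = if (length(gated)) mean(nn$dist[gated]) else Inf)
  }
  cur <- gated_mean(current)
  for (it in seq_len(max_iter)) {
    if (length(cur$gated) < 3)
      stop("ICP diverged: fewer than 3 gated matches at iteration ", it)
    trace <- c(trace, cur$mean)
    n_matches <- length(cur$gated)
    cand <- kabsch(m[cur$gated, , drop = FALSE],
                   f[cur$nn$index[cur$gated], , drop = FALSE])
    nxt <- gated_mean(cand)
    improvement <- cur$mean - nxt$mean
    if (nxt$mean < cur$mean) {  # accept only improvements: trace is monotone
      current <- cand
      cur <- nxt
    }
    if (improvement < tol_um) break
  }
  attr(current, "trace") <- trace
  attr(current, "n_matches") <- n_matches
  current
}

# closed-form least-squares rigid transform mapping `from` onto `to`
kabsch <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- crossprod(sweep(from, 2, cf), sweep(to, 2, ct))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(R, ct - as.numeric(R %*% cf))
}

#' Block-wise elastic ICP registration
#'
#' After rigid pre-alignment, the volume is tiled into cubes (default
#' 50 um edge). Blocks holding more than `min_cells` rigidly-aligned
#' moving cells are re-registered independently by gated ICP; all other
#' blocks inherit the rigid transform verbatim. The per-block residual
#' displacements at block centers are then fitted with a second-order
#' polynomial per component (quadratic smoothing), yielding a smooth
#' continuous displacement field on top of the rigid transform.
#'
#' @param fixed_cells,moving_cells cell tables or `n x 3` point matrices.
#' @param rigid the rigid pre-alignment ([rigid_transform()]).
#' @param block_um cube edge, um.
#' @param min_cells blocks with more than this many moving cells get
#'   their own ICP; others inherit the rigid transform.
#' @param gate_um ICP correspondence gate, um.
#' @return A `displacement_field`: list with `rigid`, `coef` (3 x 10
#'   quadratic coefficients of the residual field, in fixed-space
#'   coordinates), and `blocks` (per-block table: center, cell count,
#'   `own` flag, residual displacement at the center).
#' @export
elastic_register <- function(fixed_cells, moving_cells, rigid,
                             block_um = 50, min_cells = 10L, gate_um = 10) {
  f <- as_points(fixed_cells)
  m <- as_points(moving_cells)
  mr <- apply_transform(rigid, m)
  lo <- pmin(apply(f, 2, min), apply(mr, 2, min))
  hi <- pmax(apply(f, 2, max), apply(mr, 2, max))
  nb <- pmax(1L, as.integer(ceiling((hi - lo) / block_um)))
  grid <- expand.grid(ix = seq_len(nb[1]), iy = seq_len(nb[2]),
                      iz = seq_len(nb[3]))
  centers <- cbind(lo[1] + (grid$ix - 0.5) * block_um,
                   lo[2] + (grid$iy - 0.5) * block_um,
                   lo[3] + (grid$iz - 0.5) * block_um)
  bin <- function(p) {
    i <- pmin(nb[1], pmax(1L, as.integer(floor((p[, 1] - lo[1]) / block_um)) + 1L))
    j <- pmin(nb[2], pmax(1L, as.integer(floor((p[, 2] - lo[2]) / block_um)) + 1L))
    k <- pmin(nb[3], pmax(1L, as.integer(floor((p[, 3] - lo[3]) / block_um)) + 1L))
    (k - 1L) * nb[1] * nb[2] + (j - 1L) * nb[1] + i
  }
  mb <- bin(mr)
  blocks <- data.frame(cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
                       n_cells = tabulate(mb, nrow(centers)),
                       own = FALSE, ux = 0, uy = 0, uz = 0)
  for (b in seq_len(nrow(blocks))) {
    if (blocks$n_cells[b] <= min_cells) next  # inherit rigid
    sel <- which(mb == b)
    # fixed points from the block plus a half-block apron, so block-edge
    # cells can still find their counterpart
    ctr <- centers[b, ]
    near <- which(abs(f[, 1] - ctr[1]) <= block_um &
                  abs(f[, 2] - ctr[2]) <= block_um &
                  abs(f[, 3] - ctr[3]) <= block_um)
    if (length(near) < 3) next
    t_b <- tryCatch(
      icp_rigid(f[near, , drop = FALSE], mr[sel, , drop = FALSE],
                gate_um = gate_um),
      error = function(e) NULL)
    if (is.null(t_b)) next
    u <- apply_transform(t_b, matrix(ctr, 1)) - matrix(ctr, 1)
    blocks$own[b] <- TRUE
    blocks$ux[b] <- u[1]; blocks$uy[b] <- u[2]; blocks$uz[b] <- u[3]
  }
  own <- which(blocks$own)
  coef <- matrix(0, 3, 10)
  if (length(own) > 0) {
    X <- quad_basis(as.matrix(blocks[own, c("cx", "cy", "cz")]))
    U <- as.matrix(blocks[own, c("ux", "uy", "uz")])
    # quadratic needs 10 df; degrade gracefully to linear/constant fits
    use_cols <- if (length(own) >= 10) 1:10 else if (length(own) >= 4) 1:4 else 1
    fit <- qr.coef(qr(X[, use_cols, drop = FALSE]), U)
    fit[is.na(fit)] <- 0  # rank-deficient block layouts drop terms
    coef[, use_cols] <- t(fit)
  } else {
    warning("no block holds more than ", min_cells,
            " cells; returning rigid-only field")
  }
  structure(list(rigid = rigid, coef = coef, blocks = blocks,
                 block_um = block_um, min_cells = min_cells),
            class = "displacement_field")
}

#' Evaluate a displacement field at points
#'
#' Maps moving-space points through the rigid transform and adds the
#' smoothed quadratic residual (evaluated at the rigidly-transformed
#' position).
#' @param field a `displacement_field` from [elastic_register()].
#' @param points `n x 3` matrix or cell table (moving space).
#' @return transformed `n x 3` matrix (fixed space).
#' @export
evaluate_field <- function(field, points) {
  p <- apply_transform(field$rigid, as_points(points))
  p + quad_basis(p) %*% t(field$coef)
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "<displacement_field> %d blocks of %g um (%d with own ICP), rigid:\n",
    nrow(x$blocks), x$block_um, sum(x$blocks$own)))
  print(x$rigid)
  invisible(x)
}

#' Match cells across sessions
#'
#' One-to-one matching of fixed and (transformed) moving cells by mutual
#' nearest neighbors under a hard distance gate: a pair matches iff each
#' is the other's nearest neighbor and they lie within `gate_um` of each
#' other after the transform.
#'
#' @param fixed_cells,moving_cells cell tables or point matrices.
#' @param transform a [rigid_transform()] or `displacement_field` mapping
#'   moving to fixed space.
#' @param gate_um match gate, um (default 10).
#' @return A `match_set`: data frame of matches (`fixed`, `moving`,
#'   row indices; `dist_um`; per-axis signed offsets `dx_um`, `dy_um`,
#'   `dz_um` of fixed minus transformed moving), with attributes
#'   `matched_fraction` (of fixed cells), `n_fixed`, `n_moving`.
#' @export
match_cells <- function(fixed_cells, moving_cells, transform,
                        gate_um = 10) {
  f <- as_points(fixed_cells)
  m <- as_points(moving_cells)
  empty <- data.frame(fixed = integer(0), moving = integer(0),
                      dist_um = numeric(0), dx_um = numeric(0),
                      dy_um = numeric(0), dz_um = numeric(0))
  if (nrow(f) == 0 || nrow(m) == 0) {
    attr(empty, "matched_fraction") <- 0
    attr(empty, "n_fixed") <- nrow(f); attr(empty, "n_moving") <- nrow(m)
    class(empty) <- c("match_set", "data.frame")
    return(empty)
  }
  mt <- apply_transform(transform, m)
  fwd <- nn_brute(mt, f, FALSE)   # each moving -> nearest fixed
  bwd <- nn_brute(f, mt, FALSE)   # each fixed  -> nearest moving
  mov_idx <- seq_len(nrow(mt))
  mutual <- bwd$index[fwd$index[mov_idx]] == mov_idx & fwd$dist < gate_um
  res <- data.frame(fixed = fwd$index[mutual], moving = mov_idx[mutual],
                    dist_um = fwd$dist[mutual])
  off <- f[res$fixed, , drop = FALSE] - mt[res$moving, , drop = FALSE]
  res$dx_um <- off[, 1]; res$dy_um <- off[, 2]; res$dz_um <- off[, 3]
  res <- res[order(res$fixed), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "matched_fraction") <- nrow(res) / nrow(f)
  attr(res, "n_fixed") <- nrow(f); attr(res, "n_moving") <- nrow(m)
  class(res) <- c("match_set", "data.frame")
  res
}

#' @export
print.match_set <- function(x, ...) {
  cat(sprintf(
    "<match_set> %d matches (%.1f%% of %d fixed cells), mean distance %.2f um\n",
    nrow(x), 100 * attr(x, "matched_fraction"), attr(x, "n_fixed"),
    if (nrow(x)) mean(x$dist_um) else NA_real_))
  invisible(x)
}

#' Cortical elasticity map
#'
#' For each cell, the delta between elastic and rigid registration —
#' where the smoothed local deformation moved the cell beyond the global
#' rigid motion. Small coherent deltas across a subregion indicate slow
#' tissue deformation; the rendering draws one arrow per cell, colored by
#' direction, with length equal to the delta magnitude.
#'
#' @param cells moving-session cell table or point matrix.
#' @param rigid the rigid [rigid_transform()].
#' @param field the `displacement_field` from [elastic_register()].
#' @return An `elasticity_map` data frame: cell positions, delta vector
#'   (`dx_um`, `dy_um`, `dz_um`) and `magnitude_um`.
#' @export
elasticity_map <- function(cells, rigid, field) {
  p <- as_points(cells)
  pr <- apply_transform(rigid, p)
  pe <- evaluate_field(field, p)
  d <- pe - pr
  out <- data.frame(x_um = p[, 1], y_um = p[, 2], z_um = p[, 3],
                    dx_um = d[, 1], dy_um = d[, 2], dz_um = d[, 3],
                    magnitude_um = sqrt(rowSums(d^2)))
  class(out) <- c("elasticity_map", "data.frame")
  out
}

#' Plot an elasticity map as a colored quiver
#'
#' En-face (x, y) arrows, one per cell, hue encoding the in-plane delta
#' direction and arrow length the delta magnitude.
#' @param x an `elasticity_map`.
#' @param scale arrow length multiplier.
#' @param ... passed to [graphics::plot()].
#' @export
plot.elasticity_map <- function(x, scale = 5, ...) {
  hue <- (atan2(x$dy_um, x$dx_um) / (2 * pi)) %% 1
  col <- grDevices::hsv(hue, 1, 0.9)
  graphics::plot(x$x_um, x$y_um, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = "elasticity map (elastic - rigid)", ...)
  nz <- x$magnitude_um > 1e-9
  if (any(nz))
    graphics::arrows(x$x_um[nz], x$y_um[nz],
                     x$x_um[nz] + scale * x$dx_um[nz],
                     x$y_um[nz] + scale * x$dy_um[nz],
                     length = 0.04, col = col[nz])
  invisible(x)
}

#' Per-axis displacement histograms of matched cells
#'
#' Signed per-axis center-position offsets of matched cell pairs, binned
#' (default 0.5 um bins spanning +/- the match gate).
#'
#' @param match_set a `match_set` from [match_cells()].
#' @param bin_um bin width, um.
#' @param range_um half-range, um.
#' @return A `displacement_histograms` list of per-axis data frames with
#'   `mid` (bin center), `count` and `fraction`.
#' @export
displacement_histograms <- function(match_set, bin_um = 0.5, range_um = 10) {
  stopifnot(nrow(match_set) > 0)
  breaks <- seq(-range_um, range_um, by = bin_um)
  one <- function(v) {
    v <- pmin(pmax(v, -range_um + 1e-9), range_um - 1e-9)
    h <- hist(v, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts,
               fraction = h$counts / length(v))
  }
  structure(list(x = one(match_set$dx_um), y = one(match_set$dy_um),
                 z = one(match_set$dz_um), n = nrow(match_set)),
            class = "displacement_histograms")
}

#' @export
print.displacement_histograms <- function(x, ...) {
  cat(sprintf("<displacement_histograms> %d matched pairs; SD (x, y, z) = (%.2f, %.2f, %.2f) um\n",
              x$n,
              sqrt(sum(x$x$fraction * x$x$mid^2) - sum(x$x$fraction * x$x$mid)^2),
              sqrt(sum(x$y$fraction * x$y$mid^2) - sum(x$y$fraction * x$y$mid)^2),
              sqrt(sum(x$z$fraction * x$z$mid^2) - sum(x$z$fraction * x$z$mid)^2)))
  invisible(x)
}

#' @export
plot.displacement_histograms <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  for (ax in c("x", "y", "z")) {
    h <- x[[ax]]
    graphics::barplot(h$fraction, names.arg = round(h$mid, 1),
                      main = paste0(ax, "-axis offset (um)"),
                      ylab = "fraction of matched cells", border = NA)
  }
  invisible(x)
}
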