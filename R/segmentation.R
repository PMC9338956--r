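#' Segmentation parameters
#'
#' Tunable parameters of the cell-body and filament segmentation. The
#' defaults follow the method as applied to mouse visual cortex: an 8 um
#' circular kernel for layers II-IV and 13 um for layer V (set per band in
#' [layer_bands()]), a per-slice 99.5 percent response threshold, and 3D
#' acceptance rules requiring at least three consecutive axial slices,
#' at least 4 um of axial depth, a volume no larger than the equal-radius
#' sphere, and an axial spread at most twice the equivalent diameter (the
#' vessel-rejection rule).
#'
#' @param threshold_pct per-slice percentile threshold in `(0, 100)`;
#'   the top `100 - threshold_pct` percent of response pixels in each
#'   en-face slice become candidates.
#' @param min_consecutive_slices minimum number of consecutive axial
#'   slices a component must span.
#' @param min_axial_um minimum axial depth, um.
#' @param axial_gate `"2x_diameter"` (axial extent at most twice the
#'   equivalent diameter) or `"diameter"` (the stricter upper bound);
#'   `"2x_diameter"` is the vessel-rejection rule and the default.
#' @param filament_length_um length of the oriented line kernels; default
#'   twice the 8 um cell kernel.
#' @param band_margin_um extra slices pulled in around each layer band
#'   during per-band detection so cells straddling a boundary are not
#'   truncated; their centroid decides the band they report to.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold_pct = 99.5,
                                min_consecutive_slices = 3L,
                                min_axial_um = 4,
                                axial_gate = c("2x_diameter", "diameter"),
                                filament_length_um = 16,
                                band_margin_um = 15) {
  stopifnot(threshold_pct > 0, threshold_pct < 100,
            min_consecutive_slices >= 1)
  structure(list(threshold_pct = threshold_pct,
                 min_consecutive_slices = as.integer(min_consecutive_slices),
                 min_axial_um = min_axial_um,
                 axial_gate = match.arg(axial_gate),
                 filament_length_um = filament_length_um,
                 band_margin_um = band_margin_um),
            class = "segmentation_params")
}

#' Build a convolution kernel
#'
#' Disk kernels model the circular dark cross-section of a cell body; line
#' kernels model filament segments at the four canonical en-face
#' orientations. Weights are uniform over the footprint and sum to one, so
#' the response is a local mean and percentile thresholds are comparable
#' across kernel sizes.
#'
#' Disk membership uses the pixel-center radius `(d_px - 1) / 2` where
#' `d_px` is the diameter in pixels, so a disk of diameter `d` spans `d`
#' pixels across when `d` is odd, and the footprint is always odd-sized.
#'
#' @param kind `"disk"` or `"line"`.
#' @param size_um disk diameter or line length, um.
#' @param spacing `c(dz, dy, dx)` um/voxel; lateral spacing is used.
#' @param orientation for lines: 0 (horizontal, along x), 90 (vertical,
#'   along y), 45 or 135 degrees.
#' @return numeric matrix of weights summing to 1, with attribute
#'   `offsets` (data frame `dy`, `dx`, `w` of nonzero taps).
#' @export
make_kernel <- function(kind = c("disk", "line"), size_um, spacing = c(1, 1, 1),
                        orientation = 0) {
  kind <- match.arg(kind)
  dyx <- spacing[2:3]
  if (kind == "disk") {
    d_px <- size_um / min(dyx)
    if (d_px < 3) stop("kernel diameter below 3 pixels")
    r <- (d_px - 1) / 2
    half <- floor(r)
    off <- expand.grid(dy = -half:half, dx = -half:half)
    keep <- sqrt((off$dy * dyx[1])^2 + (off$dx * dyx[2])^2) <=
      r * min(dyx) + 1e-9
    off <- off[keep, , drop = FALSE]
  } else {
    l_px <- round(size_um / min(dyx))
    if (l_px < 3) stop("line length below 3 pixels")
    if (l_px %% 2 == 0) l_px <- l_px + 1
    half <- (l_px - 1) %/% 2
    s <- -half:half
    off <- switch(as.character(orientation %% 180),
                  "0"   = data.frame(dy = 0L * s, dx = s),
                  "90"  = data.frame(dy = s, dx = 0L * s),
                  "45"  = data.frame(dy = -s, dx = s),
                  "135" = data.frame(dy = s, dx = s),
                  stop("orientation must be one of 0, 45, 90, 135"))
  }
  off$w <- 1 / nrow(off)
  half_y <- max(abs(off$dy)); half_x <- max(abs(off$dx))
  k <- matrix(0, 2 * half_y + 1, 2 * half_x + 1)
  k[cbind(off$dy + half_y + 1, off$dx + half_x + 1)] <- off$w
  attr(k, "offsets") <- off
  k
}

# per-slice threshold: interpolated percentile, candidates strictly above.
# Returns a logical matrix; constant slices yield no candidates.
threshold_slice <- function(response, pct) {
  v <- as.vector(response)
  if (max(v) == min(v)) {
    warning("constant slice: threshold undefined, no candidates")
    return(matrix(FALSE, nrow(response), ncol(response)))
  }
  thr <- stats::quantile(v, pct / 100, names = FALSE, type = 7)
  response > thr
}

#' Detect per-slice candidate pixels by kernel convolution
#'
#' Each en-face slice is polarity-adjusted (inverted for dark targets, so
#' dark foci score high), convolved with the kernel (same-size output,
#' reflective border), and thresholded at the slice's own response
#' percentile: pixels strictly above the interpolated `threshold_pct`
#' percentile are candidates. Per-slice thresholding keeps detection
#' robust to depth-dependent signal falloff.
#'
#' @param vol an [oct_volume()].
#' @param kernel a kernel from [make_kernel()] (or a list of kernels, in
#'   which case the per-pixel maximum response is thresholded).
#' @param params a [segmentation_params()].
#' @param polarity `"dark"` (invert slices first) or `"bright"`.
#' @return logical 3D array of candidates, same dimensions as the volume.
#' @export
detect_candidates <- function(vol, kernel, params = segmentation_params(),
                              polarity = c("dark", "bright")) {
  stopifnot(inherits(vol, "oct_volume"))
  polarity <- match.arg(polarity)
  kernels <- if (is.list(kernel) && !is.matrix(kernel)) kernel else list(kernel)
  dims <- dim(vol$data)
  if (any(vapply(kernels, function(k) any(dim(k) > dims[1:2]), logical(1))))
    stop("kernel larger than slice")
  out <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    sl <- vol$data[, , k]
    if (polarity == "dark") sl <- max(sl) - sl
    resp <- NULL
    for (kn in kernels) {
      off <- attr(kn, "offsets")
      r <- conv2_sparse(sl, off$dy, off$dx, off$w)
      resp <- if (is.null(resp)) r else pmax(resp, r)
    }
    out[, , k] <- threshold_slice(resp, params$threshold_pct)
  }
  out
}

# per-component geometry from a label grid
component_stats <- function(labels, n_comp, vol) {
  dims <- dim(vol$data)
  sp <- vol$spacing
  idx <- which(labels > 0L)
  if (length(idx) == 0 || n_comp == 0)
    return(empty_cell_table())
  lab <- labels[idx]
  co <- arrayInd(idx, dims)  # columns: y, x, z (1-based)
  yy <- (co[, 1] - 1) * sp["y"]
  xx <- (co[, 2] - 1) * sp["x"]
  zz <- vol$depth_origin + (co[, 3] - 1) * sp["z"]
  vox_um3 <- prod(sp)
  n_vox <- tabulate(lab, n_comp)
  cy <- rowsum(yy, lab)[, 1] / n_vox
  cx <- rowsum(xx, lab)[, 1] / n_vox
  cz <- rowsum(zz, lab)[, 1] / n_vox
  zmin <- tapply(co[, 3], lab, min)
  zmax <- tapply(co[, 3], lab, max)
  n_slices <- as.integer(zmax - zmin + 1)
  # maximal en-face cross-sectional area per component
  per_slice <- tapply(seq_along(lab), list(lab, co[, 3]), length)
  a_max <- apply(per_slice, 1, max, na.rm = TRUE) * sp["y"] * sp["x"]
  r_eq <- sqrt(a_max / pi)
  data.frame(
    label = seq_len(n_comp),
    z_um = as.numeric(cz), y_um = as.numeric(cy), x_um = as.numeric(cx),
    n_voxels = n_vox,
    volume_um3 = n_vox * vox_um3,
    eq_diameter_um = 2 * as.numeric(r_eq),
    axial_extent_um = n_slices * as.numeric(sp["z"]),
    n_slices = n_slices,
    stringsAsFactors = FALSE)
}

empty_cell_table <- function() {
  data.frame(label = integer(0), z_um = numeric(0), y_um = numeric(0),
             x_um = numeric(0), n_voxels = integer(0), volume_um3 = numeric(0),
             eq_diameter_um = numeric(0), axial_extent_um = numeric(0),
             n_slices = integer(0), layer = character(0),
             stringsAsFactors = FALSE)
}

#' Filter candidate components by 3D morphological rules
#'
#' Candidates are labeled as 26-connected 3D components; with `D` the
#' expected cell diameter of the stratum (the layer-matched kernel
#' diameter), a component is accepted iff
#' (a) it spans at least `min_consecutive_slices` consecutive axial slices
#'     and at least `min_axial_um` of depth,
#' (b) its volume does not exceed the volume of the diameter-`D` sphere,
#'     `(4/3) pi (D/2)^3`, and
#' (c) its axial spread does not exceed twice the diameter, `2 D` —
#'     the rule that rejects blood vessels, which are also dark but extend
#'     far along the optical axis.
#' Condition (a)'s stricter upper bound (axial extent at most one
#' diameter) is counted and reported but only enforced when
#' `axial_gate = "diameter"`.
#'
#' @param candidates logical 3D array from [detect_candidates()].
#' @param vol the source [oct_volume()].
#' @param kernel_um expected cell (kernel) diameter `D`, um.
#' @param params a [segmentation_params()].
#' @return A `cell_mask`: list with `labels` (integer 3D array, accepted
#'   components relabeled 1..n, rejected 0), `cells` (the cell table:
#'   label, centroid um, voxel count, volume, equivalent diameter, axial
#'   extent), `rejected` (per-rule rejection counts) and `filaments`
#'   (`NULL` here).
#' @export
filter_components <- function(candidates, vol, kernel_um = 8,
                              params = segmentation_params()) {
  stopifnot(identical(dim(candidates), dim(vol$data)))
  lab <- label3d_cpp(as.logical(candidates), dim(candidates))
  n_comp <- attr(lab, "n_components")
  labels <- array(lab, dim(candidates))
  st <- component_stats(labels, n_comp, vol)
  if (nrow(st) == 0) {
    return(structure(list(labels = array(0L, dim(candidates)),
                          cells = empty_cell_table(),
                          rejected = c(axial_min = 0L, volume = 0L,
                                       axial_max = 0L, diameter_bound = 0L),
                          filaments = NULL),
                     class = "cell_mask"))
  }
  ok_a <- st$n_slices >= params$min_consecutive_slices &
    st$axial_extent_um >= params$min_axial_um
  sphere_vol <- (4 / 3) * pi * (kernel_um / 2)^3
  ok_b <- st$volume_um3 <= sphere_vol + 1e-9
  ok_c <- st$axial_extent_um <= 2 * kernel_um + 1e-9
  ok_a_upper <- st$axial_extent_um <= kernel_um + 1e-9
  keep <- ok_a & ok_b & ok_c
  if (params$axial_gate == "diameter") keep <- keep & ok_a_upper
  rejected <- c(axial_min = sum(!ok_a), volume = sum(!ok_b),
                axial_max = sum(!ok_c),
                diameter_bound = sum(keep & !ok_a_upper))
  remap <- integer(nrow(st))
  remap[st$label[keep]] <- seq_len(sum(keep))
  new_labels <- array(0L, dim(candidates))
  nz <- labels > 0L
  new_labels[nz] <- remap[labels[nz]]
  cells <- st[keep, , drop = FALSE]
  if (nrow(cells) > 0) {
    cells$label <- seq_len(nrow(cells))
    rownames(cells) <- NULL
  }
  structure(list(labels = new_labels, cells = cells, rejected = rejected,
                 filaments = NULL),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %d accepted cell bodies", nrow(x$cells)))
  if (!is.null(x$rejected))
    cat(sprintf(" (rejected: %d axial-min, %d volume, %d axial-max)",
                x$rejected[["axial_min"]], x$rejected[["volume"]],
                x$rejected[["axial_max"]]))
  cat("\n")
  if (!is.null(x$filaments))
    cat(sprintf("  filament mask: %d voxels\n", sum(x$filaments)))
  invisible(x)
}

#' Segment cell bodies across cortical layer bands
#'
#' Runs candidate detection and 3D morphological filtering separately for
#' each non-excluded layer band, using that band's kernel diameter (cell
#' size varies with cytoarchitectonic layer). Detection works on the
#' band's slices plus a margin so cells straddling a boundary are intact;
#' a cell reports to the band containing its centroid (boundary ties to
#' the shallower band), and per-band masks are merged with relabeling.
#'
#' @param vol an [oct_volume()].
#' @param bands a [layer_bands()] table covering the volume's depth range.
#' @param params a [segmentation_params()].
#' @return A `cell_mask` whose cell table carries a `layer` column.
#' @export
segment_cells <- function(vol, bands = layer_bands(),
                          params = segmentation_params()) {
  stopifnot(inherits(vol, "oct_volume"))
  depths <- slice_depths(vol)
  dims <- dim(vol$data)
  labels <- array(0L, dims)
  cells <- NULL
  rejected <- c(axial_min = 0L, volume = 0L, axial_max = 0L,
                diameter_bound = 0L)
  next_label <- 0L
  use <- bands[!bands$excluded, , drop = FALSE]
  for (i in seq_len(nrow(use))) {
    b <- use[i, ]
    ks <- which(depths >= b$depth_min - params$band_margin_um &
                depths <= b$depth_max + params$band_margin_um)
    if (length(ks) == 0) next
    sub <- oct_volume(vol$data[, , ks, drop = FALSE], spacing = vol$spacing,
                      depth_origin = depths[ks[1]])
    kern <- make_kernel("disk", b$kernel_um, vol$spacing)
    cand <- detect_candidates(sub, kern, params, polarity = "dark")
    m <- filter_components(cand, sub, b$kernel_um, params)
    rejected <- rejected + m$rejected
    if (nrow(m$cells) == 0) next
    # keep cells whose centroid lies in this band (ties go to the
    # shallower band: strictly > depth_min unless this is the first band)
    lo_open <- b$depth_min > min(bands$depth_min)
    inband <- if (lo_open) m$cells$z_um > b$depth_min & m$cells$z_um <= b$depth_max
              else m$cells$z_um >= b$depth_min & m$cells$z_um <= b$depth_max
    sel <- m$cells[inband, , drop = FALSE]
    if (nrow(sel) == 0) next
    remap <- integer(max(m$cells$label))
    remap[sel$label] <- next_label + seq_len(nrow(sel))
    sub_lab <- m$labels
    nz <- sub_lab > 0L
    keep_nz <- nz & array(sub_lab %in% sel$label, dim(sub_lab))
    # merge into the global grid; earlier (shallower) bands win collisions
    tgt <- labels[, , ks, drop = FALSE]
    fill <- keep_nz & tgt == 0L
    tgt[fill] <- remap[sub_lab[fill]]
    labels[, , ks] <- tgt
    sel$label <- remap[sel$label]
    sel$layer <- b$layer
    cells <- rbind(cells, sel)
    next_label <- next_label + nrow(sel)
  }
  if (is.null(cells)) cells <- empty_cell_table()
  rownames(cells) <- NULL
  structure(list(labels = labels, cells = cells, rejected = rejected,
                 filaments = NULL),
            class = "cell_mask")
}

#' Segment myelinated filaments with oriented line kernels
#'
#' Bright in-plane filaments are detected per en-face slice as the
#' per-pixel maximum response over four line kernels (horizontal,
#' vertical, two diagonals), thresholded at the same per-slice percentile
#' as cell detection. No 3D sphere or axial rules apply — filaments are
#' elongated by nature.
#'
#' @param vol an [oct_volume()].
#' @param params a [segmentation_params()]; `filament_length_um` sets the
#'   line kernel length.
#' @return logical 3D array marking filament voxels.
#' @export
segment_filaments <- function(vol, params = segmentation_params()) {
  kernels <- lapply(c(0, 45, 90, 135), function(th)
    make_kernel("line", params$filament_length_um, vol$spacing,
                orientation = th))
  detect_candidates(vol, kernels, params, polarity = "bright")
}
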