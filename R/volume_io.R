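#' Read a volume from a multi-page TIFF stack
#'
#' Pages are en-face slices, shallowest first. Intensities are returned as
#' doubles. If a sidecar metadata file (`<path>.yaml`, written by
#' [write_volume()]) is present, spacing, depth origin and the intensity
#' scale are taken from it; arguments override the sidecar.
#'
#' @param path TIFF file.
#' @param spacing `c(dz, dy, dx)` um/voxel; required when no sidecar exists.
#' @param depth_origin depth of the first slice, um.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path, spacing = NULL, depth_origin = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("TIFF pages have inconsistent shapes")
  meta <- read_sidecar(path)
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  if (is.null(spacing)) spacing <- meta$spacing
  if (is.null(spacing)) stop("`spacing` not given and no sidecar metadata found")
  if (is.null(depth_origin))
    depth_origin <- if (!is.null(meta$depth_origin)) meta$depth_origin else 0
  arr <- array(0, dim = c(shp[1, 1], shp[2, 1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale
  oct_volume(arr, spacing = spacing, depth_origin = depth_origin)
}

#' Write a volume as a multi-page TIFF stack
#'
#' Pages are written as 32-bit float, scaled into `[0, 1]` by the volume
#' maximum; the scale, spacing and depth origin go into a sidecar YAML file
#' (`<path>.yaml`) so [read_volume()] restores physical units. Round-trip is
#' exact to 32-bit float precision.
#'
#' @param vol an [oct_volume()].
#' @param path destination TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  mx <- max(vol$data)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(vol$data)[3]),
                  function(k) vol$data[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_sidecar(path, list(spacing = as.numeric(vol$spacing),
                           depth_origin = vol$depth_origin,
                           scale = scale))
  invisible(path)
}

#' Write a labeled integer mask as a multi-page TIFF
#'
#' Labels are stored losslessly as 16-bit integers (labels must lie in
#' 0..65535). Spacing metadata goes to the sidecar when available.
#'
#' @param mask integer 3D array `(y, x, z)`, or a `cell_mask` (its label
#'   grid is written).
#' @param path destination TIFF path.
#' @param spacing optional `c(dz, dy, dx)` stored in the sidecar.
#' @param depth_origin optional depth origin stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, spacing = NULL, depth_origin = NULL) {
  if (inherits(mask, "cell_mask")) mask <- mask$labels
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  if (is.double(mask) && any(mask != floor(mask)))
    stop("mask labels must be integers")
  if (min(mask) < 0 || max(mask) > 65535)
    stop("mask labels must lie in 0..65535")
  pages <- lapply(seq_len(dim(mask)[3]), function(k) mask[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(mask = TRUE)
  if (!is.null(spacing)) meta$spacing <- as.numeric(spacing)
  if (!is.null(depth_origin)) meta$depth_origin <- depth_origin
  write_sidecar(path, meta)
  invisible(path)
}

#' Read a labeled mask written by [write_mask()]
#'
#' @param path TIFF file.
#' @return integer 3D array `(y, x, z)`.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(round(pages[[k]] * 65535))
  arr
}

sidecar_path <- function(path) paste0(path, ".yaml")

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) yaml::read_yaml(sc) else list()
}

write_sidecar <- function(path, meta) {
  yaml::write_yaml(meta, sidecar_path(path))
}

#' Assemble a focal stack from volumes acquired at stepped focal depths
#'
#' Multi-focal acquisition steps the focal plane (e.g. every 10 um) to beat
#' the objective's limited depth of field; this assembler takes, at every
#' output depth, the en-face slice from the acquisition whose focal depth is
#' nearest, so seams fall at band midpoints. It is a simple band
#' concatenation, not a focus-stitching algorithm.
#'
#' @param volumes list of [oct_volume()] sharing the lateral grid, spacing
#'   and depth origin.
#' @param focal_depths focal depth of each volume, um; strictly increasing
#'   with a constant step.
#' @param band_halfwidth half-width of each volume's band, um; defaults to
#'   half the focal step.
#' @return An [oct_volume()] covering the same depth range.
#' @export
assemble_focal_stack <- function(volumes, focal_depths, band_halfwidth = NULL) {
  stopifnot(length(volumes) == length(focal_depths), length(volumes) >= 1)
  o <- order(focal_depths)
  volumes <- volumes[o]
  focal_depths <- as.numeric(focal_depths[o])
  if (length(volumes) == 1L) return(volumes[[1]])
  dims <- vapply(volumes, function(v) dim(v$data), integer(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("volumes must share the lateral grid")
  if (any(dims[3, ] != dims[3, 1]))
    stop("volumes must share the depth grid")
  steps <- diff(focal_depths)
  if (any(steps <= 0) || (length(steps) > 1 &&
      max(abs(steps - steps[1])) > 1e-6 * steps[1]))
    stop("focal depths must be strictly increasing with a constant step")
  if (is.null(band_halfwidth)) band_halfwidth <- steps[1] / 2
  v1 <- volumes[[1]]
  depths <- slice_depths(v1)
  # nearest focal depth; exact midpoints go to the deeper acquisition
  out <- v1$data
  for (k in seq_along(depths)) {
    d <- abs(depths[k] - focal_depths)
    pick <- max(which(d == min(d)))
    out[, , k] <- volumes[[pick]]$data[, , k]
  }
  oct_volume(out, spacing = v1$spacing, depth_origin = v1$depth_origin)
}
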