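#' Construct an OCT volume
#'
#' A volume is a 3D scalar intensity grid with physical voxel spacing and a
#' depth origin. The array is stored with dimensions `(y, x, z)` so that the
#' en-face slice at depth index `k` is the contiguous matrix `data[, , k]`;
#' `z` is the optical (depth) axis. Slice `k` (1-based) lies at physical
#' depth `depth_origin + (k - 1) * dz` micrometres below the window surface.
#'
#' @param data numeric 3D array, dimensions `(ny, nx, nz)`; finite,
#'   non-negative intensities.
#' @param spacing numeric length-3 vector `c(dz, dy, dx)` in micrometres per
#'   voxel; all strictly positive. Default 1 um isotropic.
#' @param depth_origin depth of slice 1 below the window surface, um.
#' @return An object of class `oct_volume` with elements `data`, `spacing`
#'   (named `z`, `y`, `x`) and `depth_origin`.
#' @seealso [read_volume()], [write_volume()], [slice_depths()]
#' @export
oct_volume <- function(data, spacing = c(1, 1, 1), depth_origin = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (y, x, z)")
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("volume intensities must be finite")
  if (any(data < 0)) stop("volume intensities must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (dz, dy, dx)")
  names(spacing) <- c("z", "y", "x")
  structure(
    list(data = data, spacing = spacing,
         depth_origin = as.numeric(depth_origin)),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<oct_volume> %d x %d x %d voxels (y, x, z), spacing (%g, %g, %g) um,\n",
    d[1], d[2], d[3], x$spacing["z"], x$spacing["y"], x$spacing["x"]))
  cat(sprintf("  depth %g-%g um below window; intensity range [%.3g, %.3g]\n",
              x$depth_origin,
              x$depth_origin + (d[3] - 1) * x$spacing["z"],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Physical depth of every en-face slice
#'
#' @param vol an [oct_volume()].
#' @return numeric vector, um below the window surface, one per slice.
#' @export
slice_depths <- function(vol) {
  vol$depth_origin + (seq_len(dim(vol$data)[3]) - 1) * vol$spacing["z"]
}

#' Define cortical layer depth bands
#'
#' Layers are depth bands below the cranial window. Bands must be
#' non-overlapping and in ascending depth order. Layer I is typically
#' excluded from analysis (sparse neurons, window aberrations).
#'
#' @param layer character vector of layer names, e.g. `"I"`, `"II-IV"`, `"V"`.
#' @param depth_min,depth_max band bounds, um below the window.
#' @param kernel_um circular kernel diameter used for cell segmentation in
#'   each band, um. The defaults follow the method's layer-matched sizes:
#'   8 um for layers II-IV, 13 um for layer V.
#' @param excluded logical; bands flagged `TRUE` are skipped by
#'   [segment_cells()].
#' @return A `layer_bands` data frame.
#' @examples
#' layer_bands()  # default mouse visual cortex bands
#' @export
layer_bands <- function(layer = c("I", "II-IV", "V"),
                        depth_min = c(0, 100, 400),
                        depth_max = c(100, 400, 600),
                        kernel_um = c(8, 8, 13),
                        excluded = c(TRUE, FALSE, FALSE)) {
  b <- data.frame(layer = as.character(layer),
                  depth_min = as.numeric(depth_min),
                  depth_max = as.numeric(depth_max),
                  kernel_um = as.numeric(kernel_um),
                  excluded = as.logical(excluded),
                  stringsAsFactors = FALSE)
  if (any(b$depth_max <= b$depth_min)) stop("bands must have depth_max > depth_min")
  o <- order(b$depth_min)
  b <- b[o, , drop = FALSE]
  if (nrow(b) > 1 && any(b$depth_min[-1] < b$depth_max[-nrow(b)]))
    stop("layer bands overlap")
  class(b) <- c("layer_bands", "data.frame")
  b
}

#' Assign cells to layer bands by centroid depth
#'
#' A centroid exactly on a band boundary goes to the shallower band
#' (deterministic tie-break).
#' @param depth_um numeric vector of centroid depths.
#' @param bands a [layer_bands()] table (excluded bands participate).
#' @return character vector of layer names (`NA` outside all bands).
#' @keywords internal
assign_layer <- function(depth_um, bands) {
  out <- rep(NA_character_, length(depth_um))
  for (i in seq_len(nrow(bands))) {  # ascending: shallower band wins ties
    hit <- is.na(out) & depth_um >= bands$depth_min[i] & depth_um <= bands$depth_max[i]
    out[hit] <- bands$layer[i]
  }
  out
}
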