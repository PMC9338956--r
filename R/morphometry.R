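#' Depth-blocked cell density
#'
#' Partitions the analyzed depth range into blocks (default 27 um thick),
#' anchored at the top of the range; each cell counts once, by centroid.
#' The last block may be partial and is reported with its true thickness.
#'
#' @param cells cell table (needs `z_um`).
#' @param lateral_um lateral extent `c(y, x)` of the analyzed field, um.
#' @param depth_range `c(min, max)` depth analyzed, um; defaults to the
#'   span of the cells.
#' @param block_um block thickness, um.
#' @return data frame per block: `depth_min`, `depth_max`, `thickness_um`,
#'   `n_cells`, `density_mm3` (cells per cubic millimetre).
#' @export
block_density <- function(cells, lateral_um, depth_range = NULL,
                          block_um = 27) {
  stopifnot(block_um > 0, length(lateral_um) == 2)
  if (is.null(depth_range)) depth_range <- range(cells$z_um)
  lo <- depth_range[1]; hi <- depth_range[2]
  starts <- seq(lo, hi, by = block_um)
  if (starts[length(starts)] >= hi) starts <- starts[-length(starts)]
  ends <- pmin(starts + block_um, hi)
  n <- vapply(seq_along(starts), function(i) {
    top_open <- i > 1  # block boundary cells count to the shallower block
    sum(if (top_open) cells$z_um > starts[i] & cells$z_um <= ends[i]
        else cells$z_um >= starts[i] & cells$z_um <= ends[i])
  }, integer(1))
  thick <- ends - starts
  block_mm3 <- lateral_um[1] * lateral_um[2] * thick * 1e-9
  data.frame(depth_min = starts, depth_max = ends, thickness_um = thick,
             n_cells = n, density_mm3 = n / block_mm3)
}

#' Mean nearest-neighbor distance between cells
#'
#' Each cell's Euclidean 3D distance to its nearest other cell; the
#' neighbor search is never restricted by block or layer boundaries
#' (physical distance is block-agnostic). With per-block reporting, a
#' block's value averages the NN distances of the cells whose centroid
#' falls in that block, while their neighbors may lie anywhere.
#'
#' @param cells cell table or `n x 3` point matrix.
#' @param by_block optional output of [block_density()]; adds per-block
#'   means.
#' @return list with `mean_um` (global mean; `NA` if fewer than 2 cells),
#'   `per_cell_um`, and `per_block` when requested.
#' @export
mean_nn_distance <- function(cells, by_block = NULL) {
  p <- as_points(cells)
  if (nrow(p) < 2)
    return(list(mean_um = NA_real_, per_cell_um = rep(NA_real_, nrow(p)),
                per_block = NULL))
  d <- nn_brute(p, p, TRUE)$dist
  out <- list(mean_um = mean(d), per_cell_um = d, per_block = NULL)
  if (!is.null(by_block)) {
    z <- as_points(cells)[, 3]
    pb <- by_block
    pb$mean_nn_um <- vapply(seq_len(nrow(pb)), function(i) {
      top_open <- i > 1
      sel <- if (top_open) z > pb$depth_min[i] & z <= pb$depth_max[i]
             else z >= pb$depth_min[i] & z <= pb$depth_max[i]
      if (sum(sel) == 0) NA_real_ else mean(d[sel])
    }, numeric(1))
    out$per_block <- pb
  }
  out
}

#' Mean cell-body volume
#'
#' @param cells cell table with `volume_um3`.
#' @return mean volume, um^3 (`NA` for an empty table).
#' @export
mean_cell_volume <- function(cells) {
  if (nrow(cells) == 0) return(NA_real_)
  mean(cells$volume_um3)
}

#' Depth-blocked morphometry report
#'
#' The three morphological traits the cell mask supports — density, mean
#' cell-body volume, and mean nearest-neighbor distance — in depth
#' increment blocks (default 27 um), plus per-layer aggregates.
#'
#' @param mask a `cell_mask` from [segment_cells()], or its cell table.
#' @param lateral_um lateral extent `c(y, x)` of the field, um.
#' @param depth_range analyzed depth range `c(min, max)` um; defaults to
#'   the non-excluded layer-band span when `bands` is given, else the
#'   cell span.
#' @param block_um block thickness, um.
#' @param bands optional [layer_bands()] for per-layer aggregates and the
#'   default depth range.
#' @return A `morphometry_report`: list with `blocks` (per-block density,
#'   mean volume, mean NN distance), `layers` (per-layer aggregates, when
#'   cells carry a `layer` column), and `total` counts.
#' @export
morphometry_report <- function(mask, lateral_um, depth_range = NULL,
                               block_um = 27, bands = NULL) {
  cells <- if (inherits(mask, "cell_mask")) mask$cells else mask
  if (is.null(depth_range) && !is.null(bands)) {
    use <- bands[!bands$excluded, , drop = FALSE]
    depth_range <- c(min(use$depth_min), max(use$depth_max))
  }
  blocks <- block_density(cells, lateral_um, depth_range, block_um)
  nn <- mean_nn_distance(cells, by_block = blocks)
  blocks$mean_nn_um <- if (is.null(nn$per_block)) NA_real_ else
    nn$per_block$mean_nn_um
  blocks$mean_volume_um3 <- vapply(seq_len(nrow(blocks)), function(i) {
    top_open <- i > 1
    sel <- if (top_open)
      cells$z_um > blocks$depth_min[i] & cells$z_um <= blocks$depth_max[i]
    else cells$z_um >= blocks$depth_min[i] & cells$z_um <= blocks$depth_max[i]
    if (sum(sel) == 0) NA_real_ else mean(cells$volume_um3[sel])
  }, numeric(1))
  layers <- NULL
  if (!is.null(cells$layer) && nrow(cells) > 0) {
    layers <- do.call(rbind, lapply(split(seq_len(nrow(cells)), cells$layer),
      function(ix) data.frame(
        layer = cells$layer[ix[1]],
        n_cells = length(ix),
        mean_volume_um3 = mean(cells$volume_um3[ix]),
        mean_nn_um = if (length(ix) > 0 && nrow(cells) > 1)
          mean(nn$per_cell_um[ix]) else NA_real_)))
    rownames(layers) <- NULL
  }
  structure(list(blocks = blocks, layers = layers,
                 total = nrow(cells), mean_nn_um = nn$mean_um,
                 mean_volume_um3 = mean_cell_volume(cells)),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("<morphometry_report> %d cells; mean volume %.1f um^3; mean NN distance %.2f um\n",
              x$total, x$mean_volume_um3, x$mean_nn_um))
  cat(sprintf("  %d depth blocks:\n", nrow(x$blocks)))
  print(format(x$blocks, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Depth profiles of the three morphometric traits
#'
#' @param x a `morphometry_report`.
#' @param ... ignored.
#' @export
plot.morphometry_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  mid <- (x$blocks$depth_min + x$blocks$depth_max) / 2
  graphics::plot(x$blocks$mean_volume_um3, mid, type = "b", ylim = rev(range(mid)),
                 xlab = "mean cell volume (um^3)", ylab = "depth (um)")
  graphics::plot(x$blocks$density_mm3, mid, type = "b", ylim = rev(range(mid)),
                 xlab = "density (cells/mm^3)", ylab = "depth (um)")
  graphics::plot(x$blocks$mean_nn_um, mid, type = "b", ylim = rev(range(mid)),
                 xlab = "mean NN distance (um)", ylab = "depth (um)")
  invisible(x)
}
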