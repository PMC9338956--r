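#' Score detections against phantom ground truth
#'
#' One-to-one gated matching (mutual nearest neighbors within
#' `match_radius_um`) of detected centroids against true cell centers.
#' PPV (positive predictive value, the method's "accuracy") is the
#' matched fraction of detections; recall (sensitivity) the matched
#' fraction of truth; RMSE the root-mean-square centroid error over
#' matched pairs.
#'
#' @param detected cell table or point matrix of detections.
#' @param truth truth cell table (columns `x`, `y`, `z` or `x_um`...).
#' @param match_radius_um gate, um.
#' @return An `eval_report` list: `ppv`, `recall`, `rmse_um`,
#'   `n_detected`, `n_truth`, `n_matched`. With zero detections PPV is
#'   `NA` and recall 0.
#' @export
evaluate_detection <- function(detected, truth, match_radius_um = 5) {
  nd <- nrow(as_points_safe(detected))
  nt <- nrow(as_points_safe(truth))
  if (nd == 0) {
    return(structure(list(ppv = NA_real_, recall = 0, rmse_um = NA_real_,
                          n_detected = 0L, n_truth = nt, n_matched = 0L),
                     class = "eval_report"))
  }
  ms <- match_cells(truth, detected, rigid_transform(),
                    gate_um = match_radius_um)
  nm <- nrow(ms)
  structure(list(
    ppv = nm / nd, recall = nm / nt,
    rmse_um = if (nm > 0) sqrt(mean(ms$dist_um^2)) else NA_real_,
    n_detected = nd, n_truth = nt, n_matched = nm),
    class = "eval_report")
}

as_points_safe <- function(x) {
  if ((is.data.frame(x) || is.matrix(x)) && nrow(x) == 0)
    matrix(numeric(0), 0, 3) else as_points(x)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> PPV %.3f, recall %.3f, centroid RMSE %.2f um (%d/%d detected, %d truth)\n",
    x$ppv, x$recall, x$rmse_um, x$n_matched, x$n_detected, x$n_truth))
  invisible(x)
}

#' Run the full pipeline from a config
#'
#' Orchestrates phantom generation (or volume loading), layer-wise cell
#' segmentation, filament segmentation, depth-blocked morphometry and —
#' for two-session phantom configs — rigid + elastic registration, cell
#' matching and the elasticity map. All artifacts (TIFF masks, CSV
#' tables, JSON transforms and a manifest with parameters, seed and
#' checksums) go to `config$output_dir`. Reruns with the same config are
#' reproducible: the seed drives every stochastic stage.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   `output_dir`; `seed`; exactly one of `phantom` (arguments for
#'   [phantom_config()]; add `sessions = 2` plus optional
#'   `rigid = list(theta_deg, translation)` and `elastic_coef` for a
#'   longitudinal pair) or `input` (list with `volume` path and
#'   optionally `spacing`, `depth_origin`); optional `layer_bands`
#'   (arguments for [layer_bands()]); optional `segmentation` (arguments
#'   for [segmentation_params()]); optional `morphometry`
#'   (`block_um`); optional `registration` (`block_um`, `min_cells`,
#'   `gate_um`).
#' @return the output directory, invisibly; side effect: artifact files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  bands <- do.call(layer_bands, config$layer_bands %||% list())
  params <- do.call(segmentation_params, config$segmentation %||% list())
  artifacts <- character(0)
  log_line <- function(...) message("[octcortex] ", sprintf(...))

  sessions <- list()
  truth <- NULL
  if (!is.null(config$phantom)) {
    ph_args <- config$phantom
    n_sessions <- ph_args$sessions %||% 1
    ph_args$sessions <- NULL
    rigid_spec <- ph_args$rigid; ph_args$rigid <- NULL
    elastic_coef <- ph_args$elastic_coef; ph_args$elastic_coef <- NULL
    if (!is.null(ph_args$cell_layers))
      ph_args$cell_layers <- as.data.frame(ph_args$cell_layers)
    ph_args$seed <- seed
    pc <- do.call(phantom_config, ph_args)
    if (n_sessions >= 2) {
      rigid <- if (is.null(rigid_spec)) rigid_transform() else
        rigid_z_rotation(rigid_spec$theta_deg %||% 0,
                         rigid_spec$translation %||% c(0, 0, 0))
      elastic <- if (is.null(elastic_coef)) NULL else
        quadratic_field(matrix(unlist(elastic_coef), 3, 10, byrow = TRUE))
      pair <- make_session_pair(pc, rigid, elastic)
      sessions <- list(pair$volume_t0, pair$volume_t1)
      truth <- pair$truth
      utils::write.csv(truth$cells_t0, file.path(out_dir, "truth_cells_t0.csv"),
                       row.names = FALSE)
      utils::write.csv(truth$cells_t1, file.path(out_dir, "truth_cells_t1.csv"),
                       row.names = FALSE)
    } else {
      ph <- generate_phantom(pc)
      sessions <- list(ph$volume)
      truth <- ph$truth
      utils::write.csv(truth$cells, file.path(out_dir, "truth_cells.csv"),
                       row.names = FALSE)
    }
    log_line("phantom: %d session(s), %d cells", length(sessions),
             nrow(if (is.null(truth$cells)) truth$cells_t0 else truth$cells))
  } else {
    inp <- config$input
    vols <- if (is.character(inp$volume)) as.list(inp$volume) else inp$volume
    sessions <- lapply(vols, function(p)
      read_volume(p, spacing = inp$spacing, depth_origin = inp$depth_origin))
    log_line("loaded %d volume(s)", length(sessions))
  }

  masks <- list()
  for (s in seq_along(sessions)) {
    tag <- if (length(sessions) > 1) paste0("_s", s) else ""
    m <- segment_cells(sessions[[s]], bands, params)
    log_line("session %d: %d cells (rejected %d axial-min, %d volume, %d axial-max)",
             s, nrow(m$cells), m$rejected[["axial_min"]],
             m$rejected[["volume"]], m$rejected[["axial_max"]])
    m$filaments <- segment_filaments(sessions[[s]], params)
    cells_path <- file.path(out_dir, paste0("cells", tag, ".csv"))
    utils::write.csv(m$cells, cells_path, row.names = FALSE)
    write_mask(m$labels, file.path(out_dir, paste0("mask", tag, ".tif")),
               spacing = sessions[[s]]$spacing,
               depth_origin = sessions[[s]]$depth_origin)
    write_mask(array(as.integer(m$filaments), dim(m$filaments)),
               file.path(out_dir, paste0("filaments", tag, ".tif")))
    artifacts <- c(artifacts, cells_path)
    masks[[s]] <- m
    d <- dim(sessions[[s]]$data)
    rep <- morphometry_report(
      m, lateral_um = c(d[1] * sessions[[s]]$spacing["y"],
                        d[2] * sessions[[s]]$spacing["x"]),
      block_um = (config$morphometry$block_um) %||% 27, bands = bands)
    utils::write.csv(rep$blocks,
                     file.path(out_dir, paste0("morphometry", tag, ".csv")),
                     row.names = FALSE)
  }

  if (length(sessions) >= 2) {
    reg <- config$registration %||% list()
    fixed <- masks[[1]]$cells; moving <- masks[[2]]$cells
    coarse <- coarse_register(sessions[[1]], sessions[[2]])
    rigid <- icp_rigid(fixed, moving, gate_um = reg$gate_um %||% 10,
                       init = coarse)
    field <- elastic_register(fixed, moving, rigid,
                              block_um = reg$block_um %||% 50,
                              min_cells = reg$min_cells %||% 10L,
                              gate_um = reg$gate_um %||% 10)
    matches <- match_cells(fixed, moving, field, gate_um = reg$gate_um %||% 10)
    emap <- elasticity_map(moving, rigid, field)
    log_line("registration: %.1f%% of fixed cells matched",
             100 * attr(matches, "matched_fraction"))
    jsonlite::write_json(
      list(rotation = rigid$rotation, translation = rigid$translation),
      file.path(out_dir, "transform.json"), digits = NA, matrix = "rowmajor")
    jsonlite::write_json(
      list(rigid = list(rotation = rigid$rotation,
                        translation = rigid$translation),
           quadratic_coef = field$coef, block_um = field$block_um,
           blocks = field$blocks),
      file.path(out_dir, "field.json"), digits = NA, matrix = "rowmajor",
      dataframe = "columns")
    utils::write.csv(as.data.frame(matches),
                     file.path(out_dir, "matches.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(emap),
                     file.path(out_dir, "elasticity.csv"), row.names = FALSE)
    artifacts <- c(artifacts, file.path(out_dir, "transform.json"),
                   file.path(out_dir, "matches.csv"))
  }

  if (!is.null(truth)) {
    tcells <- if (is.null(truth$cells)) truth$cells_t0 else truth$cells
    ev <- evaluate_detection(masks[[1]]$cells, tcells, match_radius_um = 5)
    jsonlite::write_json(unclass(ev), file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line("evaluation: PPV %.3f, recall %.3f", ev$ppv, ev$recall)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("octcortex")),
    seed = seed,
    config = config,
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                             pattern = "\\.(csv|json)$"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

validate_run_config <- function(config) {
  if (is.null(config$output_dir)) stop("config: `output_dir` is required")
  has_ph <- !is.null(config$phantom); has_in <- !is.null(config$input)
  if (has_ph == has_in)
    stop("config: exactly one of `phantom` or `input` must be given")
  if (!is.null(config$layer_bands)) {
    lb <- config$layer_bands
    need <- c("layer", "depth_min", "depth_max")
    if (!all(need %in% names(lb)))
      stop("config: `layer_bands` needs layer, depth_min, depth_max")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
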