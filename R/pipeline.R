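#' Pipeline configuration
#'
#' A single serialisable description of an end-to-end run: input volumes,
#' optional preprocessing, block-matching affine stage, FFD stage,
#' evaluation inputs and the output directory. Defaults are the platform's
#' tuned parameter set (block 20/search 30/overlap 3/3 levels/30 iterations;
#' grid 5, 3 levels, 500 iterations, tolerance 0.001, w1 = 0.045,
#' w2 = 0.055, 256 bins). Validation rejects `w1 + w2 >= 1` outright and
#' warns for weights above 0.1 (known to degrade registration).
#'
#' @param ref,mov input volume paths (NIfTI/TIFF).
#' @param out_dir run directory (created).
#' @param preprocess list: `gray` (logical), `window` (lo, hi),
#'   `resample` (mm triple), `crop` (2x3 bounds) — applied to both inputs
#'   where meaningful.
#' @param init_translate initial mm translation (stand-in for manual
#'   pre-alignment).
#' @param affine a [BlockMatchConfig()] (or NULL to skip the stage).
#' @param ffd an [FFDConfig()] (or NULL to skip).
#' @param evaluate list: optional `mask_ref`, `mask_mov` (paths),
#'   `landmarks_ref`, `landmarks_mov` (CSV paths), `roi` (path, for Jacobian
#'   ROI stats).
#' @param seed integer recorded for provenance (the registration itself is
#'   deterministic).
#' @return A `cryo_pipelineconfig` list.
#' @export
PipelineConfig <- function(ref, mov, out_dir, preprocess = list(),
                           init_translate = c(0, 0, 0),
                           affine = BlockMatchConfig(), ffd = FFDConfig(),
                           evaluate = list(), seed = 1L) {
  cfg <- structure(list(ref = ref, mov = mov, out_dir = out_dir,
                        preprocess = preprocess,
                        init_translate = as.numeric(init_translate),
                        affine = affine, ffd = ffd, evaluate = evaluate,
                        seed = as.integer(seed)),
                   class = "cryo_pipelineconfig")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$ffd)) {
    if (cfg$ffd$w1 + cfg$ffd$w2 >= 1)
      stop("invalid FFD weights: w1 + w2 must be < 1")
  }
  invisible(cfg)
}

read_mask_file <- function(path) {
  v <- read_volume(path)
  BinaryMask(v$data > 0.5, v$spacing, v$origin)
}

#' Run the full registration + evaluation pipeline
#'
#' Stages, in order: read, preprocess, block-matching rigid/affine, FFD,
#' one-step resampling of the moving volume, Jacobian map, evaluation
#' (Dice / volume difference / surface distance on masks, landmark error),
#' QC checkerboards, and a JSON report with provenance (config echo, seed,
#' package version). Rerunning with an identical config reproduces an
#' identical report.
#'
#' @param cfg a [PipelineConfig()].
#' @param verbose print stage progress.
#' @return invisibly, the report list (also written to
#'   `<out_dir>/report.json`).
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage_log <- list()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  ref <- read_volume(cfg$ref)
  mov <- read_volume(cfg$mov)
  pp <- cfg$preprocess
  prep <- function(v) {
    if (isTRUE(pp$gray)) v <- rgb_to_gray(v)
    if (!is.null(pp$window)) v <- window_to_byte(v, WindowSpec(pp$window[1], pp$window[2]))
    if (!is.null(pp$crop)) v <- crop_to_box(v, matrix(as.integer(pp$crop), 2, 3))
    if (!is.null(pp$resample)) v <- lanczos_resample(v, pp$resample)
    v
  }
  ref <- prep(ref); mov <- prep(mov)
  stage_log$preprocess <- tic() - t0
  init <- AffineTransform(translation = cfg$init_translate)
  t_aff <- init
  if (!is.null(cfg$affine)) {
    say("affine stage")
    t1 <- tic()
    t_aff <- register_affine_multiscale(ref, mov, cfg$affine, init)
    stage_log$affine <- tic() - t1
    write_affine(t_aff, file.path(cfg$out_dir, "affine.json"))
  }
  t_ffd <- NULL
  trace <- NULL
  if (!is.null(cfg$ffd)) {
    say("ffd stage")
    t1 <- tic()
    t_ffd <- optimize_ffd(ref, mov, t_aff, cfg$ffd)
    stage_log$ffd <- tic() - t1
    trace <- attr(t_ffd, "trace")
    write_ffd(t_ffd, file.path(cfg$out_dir, "ffd.json"))
    jac <- jacobian_det_map(t_ffd)
    write_volume(jac, file.path(cfg$out_dir, "jacobian.nii.gz"))
  }
  say("resampling")
  registered <- compose_and_resample(mov, affine = t_aff, ffd = t_ffd,
                                     out_grid = ref)
  write_volume(registered, file.path(cfg$out_dir, "registered.nii.gz"))
  # QC checkerboards in three orthogonal planes
  for (pl in c("axial", "coronal", "sagittal")) {
    cb <- checkerboard(ref, registered, tile_mm = 8 * min(ref$spacing),
                       plane = pl)
    write_image2d(cb, file.path(cfg$out_dir, paste0("checkerboard_", pl, ".tif")))
  }
  # evaluation
  metrics <- list()
  ev <- cfg$evaluate
  if (!is.null(ev$mask_ref) && !is.null(ev$mask_mov)) {
    m_ref <- read_mask_file(ev$mask_ref)
    m_movvol <- read_volume(ev$mask_mov)
    warp_mask <- function(aff, ffd) {
      w <- compose_and_resample(Volume(array(as.numeric(m_movvol$data > 0.5),
                                             vol_shape(m_movvol)),
                                       m_movvol$spacing, m_movvol$origin),
                                affine = aff, ffd = ffd, out_grid = ref)
      BinaryMask(w$data > 0.5, ref$spacing, ref$origin)
    }
    m_aff <- warp_mask(t_aff, NULL)
    metrics$affine <- list(dice = dice(m_ref, m_aff),
                           volume_difference = volume_difference(m_ref, m_aff),
                           surface_distance_mm = mean_surface_distance(m_ref, m_aff))
    if (!is.null(t_ffd)) {
      m_f <- warp_mask(t_aff, t_ffd)
      metrics$ffd <- list(dice = dice(m_ref, m_f),
                          volume_difference = volume_difference(m_ref, m_f),
                          surface_distance_mm = mean_surface_distance(m_ref, m_f))
    }
  }
  if (!is.null(ev$landmarks_ref) && !is.null(ev$landmarks_mov)) {
    lr <- read_landmarks(ev$landmarks_ref)
    lm <- read_landmarks(ev$landmarks_mov)
    mapped <- transform_points(lr$points, affine = t_aff, ffd = t_ffd)
    le <- landmark_error(LandmarkSet(mapped, lr$labels), lm)
    metrics$landmark_error_mm <- list(mean = le$mean, sd = le$sd)
  }
  if (!is.null(ev$roi) && !is.null(t_ffd)) {
    roi <- read_mask_file(ev$roi)
    jac <- jacobian_det_map(t_ffd)
    metrics$jacobian_roi <- roi_stats(jac, roi)
  }
  report <- list(
    config = list(ref = cfg$ref, mov = cfg$mov, seed = cfg$seed,
                  init_translate = cfg$init_translate,
                  affine = unclass(cfg$affine), ffd = unclass(cfg$ffd)),
    provenance = list(package = "cryoreg",
                      version = as.character(utils::packageVersion("cryoreg")),
                      sd_convention = "population (divide by N)"),
    metrics = metrics,
    cost_trace = trace,
    stage_seconds = lapply(stage_log, function(x) round(x, 3)))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Grid search over the FFD regularization weights
#'
#' Reruns the FFD stage for every `(w1, w2)` pair and evaluates mask overlap
#' metrics, reproducing the shape of the platform's weight-tuning
#' experiment at whatever scale the inputs have. Rows with a weight above
#' 0.1 are flagged (`degraded_range = TRUE`). Folding is tolerated during
#' the search (clamped log-Jacobian) so unregularised corners still produce
#' a row.
#'
#' @param ref,mov volumes (`[0,255]` intensities) on their own grids.
#' @param init affine pre-alignment.
#' @param mask_ref reference-frame evaluation [BinaryMask()].
#' @param mask_mov moving-frame evaluation mask (warped per run).
#' @param w1_values,w2_values numeric vectors of weights.
#' @param cfg base [FFDConfig()]; its `w1`/`w2` are overridden per run.
#' @return data.frame with w1, w2, vd, dice, surface_distance_mm,
#'   degraded_range.
#' @export
grid_search_weights <- function(ref, mov, init, mask_ref, mask_mov,
                                w1_values, w2_values, cfg = FFDConfig()) {
  rows <- list()
  mov_mask_vol <- Volume(array(as.numeric(mask_mov$data), vol_shape(mask_mov)),
                         mask_mov$spacing, mask_mov$origin)
  for (w1 in w1_values) for (w2 in w2_values) {
    cfg_i <- cfg
    cfg_i$w1 <- w1; cfg_i$w2 <- w2
    if (w1 + w2 >= 1) stop("invalid grid point: w1 + w2 must be < 1")
    t_ffd <- optimize_ffd(ref, mov, init, cfg_i, allow_folding = TRUE)
    w <- compose_and_resample(mov_mask_vol, affine = init, ffd = t_ffd,
                              out_grid = ref)
    m <- BinaryMask(w$data > 0.5, ref$spacing, ref$origin)
    rows[[length(rows) + 1L]] <- data.frame(
      w1 = w1, w2 = w2,
      vd = volume_difference(mask_ref, m),
      dice = dice(mask_ref, m),
      surface_distance_mm = mean_surface_distance(mask_ref, m),
      degraded_range = w1 > 0.1 || w2 > 0.1)
  }
  do.call(rbind, rows)
}
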