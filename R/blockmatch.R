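#' Block-matching registration configuration
#'
#' Defaults follow the platform's tuned values: 20-voxel blocks searched in a
#' 30-voxel neighbourhood, 3-voxel overlap between adjacent blocks
#' (stride = block - 3), 3 multiscale levels, up to 30 fit-rematch iterations
#' per level, the top 50% of blocks by reference variance matched, and 50%
#' trimming in the robust model fit.
#'
#' @param block_size voxels per axis of a matching block.
#' @param search_size voxels per axis of the search neighbourhood
#'   (>= block_size; the shift range is +-(search_size - block_size)/2).
#' @param block_overlap voxels of overlap between adjacent blocks.
#' @param n_levels multiscale levels (each downsamples by 2).
#' @param n_iterations maximum fit-transform-rematch cycles per level.
#' @param variance_keep_fraction fraction of blocks kept, by descending
#'   reference-block variance.
#' @param reject_fraction fraction of matches discarded in trimmed least
#'   squares.
#' @param model `"rigid"` or `"affine"`.
#' @return A `cryo_bmconfig` object.
#' @export
BlockMatchConfig <- function(block_size = 20L, search_size = 30L,
                             block_overlap = 3L, n_levels = 3L,
                             n_iterations = 30L, variance_keep_fraction = 0.5,
                             reject_fraction = 0.5,
                             model = c("affine", "rigid")) {
  model <- match.arg(model)
  if (search_size < block_size) stop("search_size must be >= block_size")
  if (block_overlap >= block_size) stop("block_overlap must be < block_size")
  if (variance_keep_fraction <= 0 || variance_keep_fraction > 1)
    stop("variance_keep_fraction must lie in (0, 1]")
  if (reject_fraction < 0 || reject_fraction >= 1)
    stop("reject_fraction must lie in [0, 1)")
  structure(list(block_size = as.integer(block_size),
                 search_size = as.integer(search_size),
                 block_overlap = as.integer(block_overlap),
                 n_levels = as.integer(n_levels),
                 n_iterations = as.integer(n_iterations),
                 variance_keep_fraction = variance_keep_fraction,
                 reject_fraction = reject_fraction, model = model),
            class = "cryo_bmconfig")
}

#' Absolute normalized cross-correlation of two blocks
#'
#' The absolute value of the Pearson correlation of the flattened
#' intensities. Taking the absolute value matches edges regardless of their
#' contrast polarity, which is what makes this similarity usable across
#' modalities when high-variance (edge-rich) blocks are selected.
#'
#' @param block_a,block_b numeric arrays of identical shape with nonzero
#'   variance.
#' @return a score in `[0, 1]`.
#' @export
abs_ncc <- function(block_a, block_b) {
  a <- as.numeric(block_a); b <- as.numeric(block_b)
  if (length(a) != length(b)) stop("blocks must have identical shapes")
  if (stats::var(a) <= 1e-12 || stats::var(b) <= 1e-12)
    stop("zero-variance block is unmatchable")
  abs(stats::cor(a, b))
}

#' Estimate a local displacement field by block matching
#'
#' Blocks are tiled over the reference at stride `block_size - block_overlap`;
#' the top `variance_keep_fraction` by reference variance are retained and
#' each is searched exhaustively over integer voxel shifts, maximising
#' [abs_ncc()]. Displacements are reported in mm. If `mov` is not on the
#' reference grid it is first resampled there.
#'
#' @param ref,mov scalar [Volume()]s overlapping in physical space.
#' @param cfg a [BlockMatchConfig()].
#' @return A `cryo_blockmatchset`: physical block centers, mm displacement
#'   vectors, |NCC| scores and block variances.
#' @export
block_displacement_field <- function(ref, mov, cfg = BlockMatchConfig()) {
  if (!identical(vol_shape(ref), vol_shape(mov)) ||
      max(abs(ref$spacing - mov$spacing)) > 1e-9 ||
      max(abs(ref$origin - mov$origin)) > 1e-9) {
    mov <- resample_affine(mov, AffineTransform(), ref)
  }
  half <- (cfg$search_size - cfg$block_size) %/% 2L
  stride <- cfg$block_size - cfg$block_overlap
  m <- block_match_cpp(as.numeric(ref$data), as.numeric(mov$data),
                       as.integer(vol_shape(ref)), cfg$block_size, half,
                       stride, cfg$variance_keep_fraction)
  if (nrow(m) == 0L) stop("no blocks survived the variance filter")
  center_vox <- m[, 1:3, drop = FALSE] + (cfg$block_size - 1) / 2
  structure(list(
    centers = voxel_to_phys(ref, center_vox),
    displacements = sweep(m[, 4:6, drop = FALSE], 2, ref$spacing, "*"),
    scores = m[, 7],
    variances = m[, 8]
  ), class = "cryo_blockmatchset")
}

least_squares_fit <- function(p, q, model) {
  n <- nrow(p)
  if (model == "rigid") {
    pc <- colMeans(p); qc <- colMeans(q)
    H <- crossprod(sweep(p, 2, pc), sweep(q, 2, qc))
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    AffineTransform(R, qc - as.numeric(R %*% pc))
  } else {
    X <- cbind(p, 1)
    sv <- svd(sweep(p, 2, colMeans(p)))$d
    if (sv[3] < 1e-9 * max(sv[1], 1))
      stop("degenerate geometry: block centers are coplanar")
    beta <- qr.solve(X, q)            # 4 x 3
    AffineTransform(t(beta[1:3, , drop = FALSE]), beta[4, ])
  }
}

#' Robust transform fit by trimmed least squares
#'
#' Fits `model` to point pairs (center -> center + displacement), then
#' repeatedly keeps the `1 - reject_fraction` fraction of pairs with the
#' smallest residuals and refits until the kept set stabilises. With
#' `reject_fraction = 0` this reduces to ordinary least squares.
#'
#' @param matches a `cryo_blockmatchset` (or list with `centers` and
#'   `displacements` matrices in mm).
#' @param model `"rigid"` (rotation + translation) or `"affine"`.
#' @param reject_fraction fraction of worst pairs discarded each round.
#' @return An [AffineTransform()] mapping reference mm to moving mm.
#' @export
fit_transform_trimmed <- function(matches, model = c("affine", "rigid"),
                                  reject_fraction = 0.5) {
  model <- match.arg(model)
  p <- rbind_points(matches$centers)
  q <- p + rbind_points(matches$displacements)
  n <- nrow(p)
  min_n <- if (model == "rigid") 6L else 12L
  n_keep <- max(min_n, ceiling((1 - reject_fraction) * n))
  if (n < min_n)
    stop("need at least ", min_n, " matches for a ", model, " fit, got ", n)
  keep <- seq_len(n)
  for (it in 1:50) {
    fit <- least_squares_fit(p[keep, , drop = FALSE], q[keep, , drop = FALSE], model)
    res <- rowSums((affine_apply(fit, p) - q)^2)
    new_keep <- order(res)[seq_len(n_keep)]
    if (setequal(new_keep, keep)) break
    keep <- new_keep
  }
  fit
}

bbox_corners <- function(v) {
  s <- (vol_shape(v) - 1) * v$spacing
  as.matrix(expand.grid(c(0, s[1]), c(0, s[2]), c(0, s[3]))) +
    matrix(v$origin, 8, 3, byrow = TRUE)
}

#' Multiscale rigid/affine registration by block matching
#'
#' Coarse-to-fine over `cfg$n_levels` (downsampling by 2 per level). At each
#' level, up to `cfg$n_iterations` fit-transform-rematch cycles are run for a
#' rigid stage and then, if `cfg$model == "affine"`, an affine stage; a cycle
#' resamples the moving volume through the current estimate, block matches
#' against the reference, and composes the fitted incremental transform.
#' Cycles stop early once the incremental update moves no corner of the
#' volume by more than 0.1 voxel.
#'
#' @param ref,mov scalar [Volume()]s.
#' @param cfg a [BlockMatchConfig()].
#' @param init initial [AffineTransform()] giving rough overlap (e.g. a
#'   manual translation).
#' @param verbose print per-level progress.
#' @return The composed [AffineTransform()] (reference mm -> moving mm).
#' @export
register_affine_multiscale <- function(ref, mov, cfg = BlockMatchConfig(),
                                       init = AffineTransform(),
                                       verbose = FALSE) {
  t_cur <- init
  stages <- if (cfg$model == "affine") c("rigid", "affine") else "rigid"
  for (level in (cfg$n_levels - 1L):0L) {
    f <- 2L^level
    shape_l <- vol_shape(ref) %/% f
    if (any(shape_l < cfg$block_size)) next
    ref_l <- downsample_volume(ref, f)
    corners <- bbox_corners(ref_l)
    conv_tol <- 0.1 * min(ref_l$spacing)
    for (stage in stages) {
      # fits on very few matches are unstable (a bad coarse fit can flip the
      # whole registration into a reflected basin); demand a safety margin
      # over the bare feasibility minimum before trusting a level
      min_matches <- if (stage == "rigid") 12L else 16L
      for (iter in seq_len(cfg$n_iterations)) {
        mov_t <- resample_affine(mov, t_cur, ref_l)
        matches <- tryCatch(block_displacement_field(ref_l, mov_t, cfg),
                            error = function(e) NULL)
        if (is.null(matches) || length(matches$scores) < min_matches) break
        dt <- tryCatch(
          fit_transform_trimmed(matches, stage, cfg$reject_fraction),
          error = function(e) NULL)
        if (is.null(dt)) break
        upd <- max(sqrt(rowSums((affine_apply(dt, corners) - corners)^2)))
        t_cur <- affine_compose(t_cur, dt)
        if (verbose)
          message(sprintf("level %d %s iter %d: update %.4f mm (%d matches)",
                          level, stage, iter, upd, length(matches$scores)))
        if (upd < conv_tol) break
      }
    }
  }
  t_cur
}
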