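# Seeded synthetic phantoms with analytic ground truth. These stand in for
# study data (whole-mouse cryo/MRI/CT volumes are not deposited with the
# platform): every generator is a pure function of its spec, so a fixed seed
# reproduces byte-identical fixtures, and the true transforms / masks /
# landmarks are returned alongside the images.

#' Phantom specification for a multimodal 3D pair
#'
#' The defaults describe a desk-scale stand-in for a mouse torso: a
#' 96 x 64 x 64 volume at 0.2 mm spacing holding an ellipsoidal body with
#' `n_organs` textured ellipsoidal organs and bright vessel-like curves
#' (block matching relies on such edges), deformed by a known affine plus a
#' smooth B-spline warp, intensity-remapped to emulate a second modality,
#' with additive Gaussian noise.
#'
#' @param seed integer RNG seed.
#' @param shape voxel triple.
#' @param spacing mm (scalar or triple).
#' @param n_organs number of internal organs.
#' @param rotation_deg truth rotation about z (degrees).
#' @param scale truth anisotropic scale triple.
#' @param translation_mm truth translation.
#' @param warp_amplitude_vox peak truth nonrigid displacement, in voxels
#'   (must stay below `warp_grid_vox` for invertibility).
#' @param warp_grid_vox control spacing of the truth warp (voxels).
#' @param intensity_remap `"none"`, `"monotone"` (gamma-style) or
#'   `"inverted"` (monotone plus contrast inversion inside one organ).
#' @param noise_sd additive Gaussian noise, 8-bit intensity units.
#' @param lung_like add a low-intensity organ with doubled local warp
#'   amplitude (the hardest region to register, for weight-tuning
#'   experiments).
#' @param n_landmarks paired ground-truth landmarks.
#' @return A `cryo_phantomspec` list.
#' @export
PhantomSpec <- function(seed = 1L, shape = c(96L, 64L, 64L), spacing = 0.2,
                        n_organs = 4L, rotation_deg = 0, scale = c(1, 1, 1),
                        translation_mm = c(0, 0, 0), warp_amplitude_vox = 0,
                        warp_grid_vox = 8L,
                        intensity_remap = c("none", "monotone", "inverted"),
                        noise_sd = 3, lung_like = FALSE, n_landmarks = 20L) {
  intensity_remap <- match.arg(intensity_remap)
  spacing <- rep(spacing, length.out = 3)
  if (warp_amplitude_vox >= warp_grid_vox)
    stop("warp amplitude must stay below the truth-lattice spacing")
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 spacing = spacing, n_organs = as.integer(n_organs),
                 rotation_deg = rotation_deg,
                 scale = rep(scale, length.out = 3),
                 translation_mm = translation_mm,
                 warp_amplitude_vox = warp_amplitude_vox,
                 warp_grid_vox = as.integer(warp_grid_vox),
                 intensity_remap = intensity_remap, noise_sd = noise_sd,
                 lung_like = lung_like, n_landmarks = as.integer(n_landmarks)),
            class = "cryo_phantomspec")
}

# analytic anatomy: returns closures evaluating intensity and organ
# membership at arbitrary physical points
phantom_anatomy <- function(spec) {
  sh <- spec$shape; sp <- spec$spacing
  ext <- (sh - 1) * sp
  ctr <- ext / 2
  body_ax <- ext * 0.42
  n_org <- spec$n_organs + as.integer(spec$lung_like)
  # organ centers spread along the long axis, jittered
  org <- list()
  base_int <- seq(70, 220, length.out = max(n_org, 2))
  for (k in seq_len(n_org)) {
    along <- (k - 0.5) / n_org
    cen <- c(ext[1] * (0.18 + 0.64 * along),
             ctr[2] + stats::runif(1, -0.15, 0.15) * ext[2],
             ctr[3] + stats::runif(1, -0.15, 0.15) * ext[3])
    ax <- c(ext[1] / n_org * stats::runif(1, 0.38, 0.5),
            body_ax[2] * stats::runif(1, 0.35, 0.55),
            body_ax[3] * stats::runif(1, 0.35, 0.55))
    org[[k]] <- list(center = cen, axes = ax, intensity = base_int[k],
                     lung = spec$lung_like && k == n_org)
  }
  if (spec$lung_like) org[[n_org]]$intensity <- 40
  # smooth texture: coarse seeded grid, trilinearly interpolated
  tex_step <- 6L
  tex_dim <- sh %/% tex_step + 2L
  tex <- array(stats::rnorm(prod(tex_dim), 0, 18), tex_dim)
  # vessel-like bright curves: quadratic Beziers inside the body
  curves <- lapply(1:3, function(i) {
    p <- matrix(stats::runif(9, 0.2, 0.8), 3, 3)
    sweep(p, 2, ext, "*")
  })
  curve_pts <- do.call(rbind, lapply(curves, function(cp) {
    tt <- seq(0, 1, length.out = 60)
    (1 - tt)^2 %o% cp[1, ] + 2 * tt * (1 - tt) %o% cp[2, ] + tt^2 %o% cp[3, ]
  }))
  ellip <- function(pts, cen, ax) {
    d2 <- ((pts[, 1] - cen[1]) / ax[1])^2 + ((pts[, 2] - cen[2]) / ax[2])^2 +
          ((pts[, 3] - cen[3]) / ax[3])^2
    1 / (1 + exp((d2 - 1) * 12))    # soft edge
  }
  intensity_at <- function(pts) {
    pts <- rbind_points(pts)
    v <- 30 * ellip(pts, ctr, body_ax)
    for (o in org) v <- v + (o$intensity - 30) * ellip(pts, o$center, o$axes) *
        ellip(pts, ctr, body_ax)
    # texture inside body
    tx <- sweep(pts, 2, sp * tex_step, "/")
    v <- v + trilinear_sample_cpp(as.numeric(tex), tex_dim, tx, 0) *
      ellip(pts, ctr, body_ax)
    # vessels: gaussian tube profile around polyline points
    dmin <- rep(Inf, nrow(pts))
    for (i in seq_len(nrow(curve_pts))) {
      d2 <- (pts[, 1] - curve_pts[i, 1])^2 + (pts[, 2] - curve_pts[i, 2])^2 +
            (pts[, 3] - curve_pts[i, 3])^2
      dmin <- pmin(dmin, d2)
    }
    v + 70 * exp(-dmin / (2 * (1.5 * sp[1])^2)) * ellip(pts, ctr, body_ax)
  }
  organ_at <- function(pts, k) {
    ellip(rbind_points(pts), org[[k]]$center, org[[k]]$axes) > 0.5
  }
  lung_weight <- function(pts) {
    if (!spec$lung_like) return(rep(0, nrow(rbind_points(pts))))
    ellip(rbind_points(pts), org[[n_org]]$center, org[[n_org]]$axes * 1.4)
  }
  list(intensity = intensity_at, organ = organ_at, n_organs = n_org,
       body = function(pts) ellip(rbind_points(pts), ctr, body_ax) > 0.5,
       lung_weight = lung_weight, center = ctr, extent = ext)
}

phantom_truth_affine <- function(spec) {
  th <- spec$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  M <- R %*% diag(spec$scale)
  ctr <- (spec$shape - 1) * spec$spacing / 2
  # rotate/scale about the volume center, then translate
  AffineTransform(M, ctr - as.numeric(M %*% ctr) + spec$translation_mm)
}

phantom_truth_ffd <- function(spec, anatomy) {
  dom <- list(shape = spec$shape, spacing = spec$spacing, origin = c(0, 0, 0))
  t0 <- FFDTransform(grid_spacing = spec$warp_grid_vox, domain = dom)
  if (spec$warp_amplitude_vox <= 0) return(t0)
  cdim <- dim(t0$coef)
  coef <- array(stats::rnorm(prod(cdim)), cdim)
  if (spec$lung_like) {
    # double the displacement amplitude around the lung-like organ
    cp <- as.matrix(expand.grid((seq_len(cdim[1]) - 2) * spec$warp_grid_vox,
                                (seq_len(cdim[2]) - 2) * spec$warp_grid_vox,
                                (seq_len(cdim[3]) - 2) * spec$warp_grid_vox))
    wl <- 1 + anatomy$lung_weight(sweep(cp, 2, spec$spacing, "*"))
    for (k in 1:3) coef[, , , k] <- coef[, , , k] * array(wl, cdim[1:3])
  }
  # scale so the peak displacement magnitude is warp_amplitude_vox voxels
  probe <- ffd_field_cpp(as.numeric(coef), cdim[1:3],
                         as.integer(rep(spec$warp_grid_vox, 3)),
                         as.integer(spec$shape))
  peak <- max(sqrt(rowSums(matrix(probe, ncol = 3)^2)))
  coef <- coef * (spec$warp_amplitude_vox / peak)
  for (k in 1:3) coef[, , , k] <- coef[, , , k] * spec$spacing[k]
  FFDTransform(coef, spec$warp_grid_vox, dom)
}

# numerically invert T(x) = A(x + u(x)) at points y by fixed-point iteration;
# iterates are clamped to the padded domain because the spline extrapolation
# outside the lattice is not a contraction
phantom_invert_points <- function(y, affine, ffd, iters = 20L) {
  z <- affine_apply(affine_invert(affine), y)
  ext <- (ffd$domain$shape - 1) * ffd$domain$spacing
  lo <- ffd$domain$origin - 0.2 * ext
  hi <- ffd$domain$origin + 1.2 * ext
  clamp <- function(p) {
    for (k in 1:3) p[, k] <- pmin(pmax(p[, k], lo[k]), hi[k])
    p
  }
  x <- clamp(z)
  for (i in seq_len(iters)) x <- clamp(z - ffd_displacement(ffd, x))
  x
}

remap_intensity <- function(v, mode, invert_sel = NULL) {
  out <- switch(mode,
    none = v,
    monotone = 255 * (pmax(v, 0) / 255)^0.7,
    inverted = 255 * (pmax(v, 0) / 255)^0.7)
  if (identical(mode, "inverted") && !is.null(invert_sel))
    out[invert_sel] <- 255 - out[invert_sel]
  out
}

#' Generate a multimodal phantom pair with ground truth
#'
#' The reference volume samples the analytic anatomy on its grid; the moving
#' volume is the anatomy observed through the truth transform
#' `T(x) = A(x + u(x))` (affine after B-spline warp, so a pull-back of the
#' moving volume through `T` reproduces the reference), with an optional
#' modality-style intensity remap and Gaussian noise. Landmarks are anatomy
#' points paired through `T`. Organ masks are produced in both frames.
#'
#' @param spec a [PhantomSpec()].
#' @return list with `ref`, `mov` ([Volume()]s in `[0,255]`), `truth`
#'   (`affine`, `ffd`), `landmarks` (`ref`, `mov` [LandmarkSet()]s),
#'   `masks` (`body`, `organs`, `organs_mov` lists of [BinaryMask()]),
#'   and the `spec`.
#' @export
make_phantom_pair <- function(spec = PhantomSpec()) {
  set.seed(spec$seed)
  anat <- phantom_anatomy(spec)
  affine <- phantom_truth_affine(spec)
  ffd <- phantom_truth_ffd(spec, anat)
  sh <- spec$shape; sp <- spec$spacing
  grid <- as.matrix(expand.grid(0:(sh[1] - 1), 0:(sh[2] - 1), 0:(sh[3] - 1)))
  pts <- sweep(grid, 2, sp, "*")
  ref_v <- anat$intensity(pts)
  ref <- Volume(array(pmin(pmax(ref_v + stats::rnorm(length(ref_v), 0, spec$noise_sd), 0), 255), sh), sp)
  # moving volume: anatomy at T^-1(y)
  xinv <- phantom_invert_points(pts, affine, ffd)
  mov_v <- anat$intensity(xinv)
  inv_sel <- if (spec$intensity_remap == "inverted") anat$organ(xinv, 1) else NULL
  mov_v <- remap_intensity(mov_v, spec$intensity_remap, inv_sel)
  mov <- Volume(array(pmin(pmax(mov_v + stats::rnorm(length(mov_v), 0, spec$noise_sd), 0), 255), sh), sp)
  # landmarks: random anatomy points well inside the body
  lm_ref <- NULL
  guard <- 0
  while (is.null(lm_ref) || nrow(lm_ref) < spec$n_landmarks) {
    cand <- cbind(stats::runif(200, 0.15, 0.85) * anat$extent[1],
                  stats::runif(200, 0.2, 0.8) * anat$extent[2],
                  stats::runif(200, 0.2, 0.8) * anat$extent[3])
    keep <- anat$body(cand)
    lm_ref <- rbind(lm_ref, cand[keep, , drop = FALSE])
    if ((guard <- guard + 1) > 50) stop("could not place landmarks in body")
  }
  lm_ref <- lm_ref[seq_len(spec$n_landmarks), , drop = FALSE]
  lm_mov <- affine_apply(affine, lm_ref + ffd_displacement(ffd, lm_ref))
  # masks
  organs <- lapply(seq_len(anat$n_organs), function(k)
    BinaryMask(array(anat$organ(pts, k), sh), sp))
  organs_mov <- lapply(seq_len(anat$n_organs), function(k)
    BinaryMask(array(anat$organ(xinv, k), sh), sp))
  body <- BinaryMask(array(anat$body(pts), sh), sp)
  list(ref = ref, mov = mov,
       truth = list(affine = affine, ffd = ffd),
       landmarks = list(ref = LandmarkSet(lm_ref), mov = LandmarkSet(lm_mov)),
       masks = list(body = body, organs = organs, organs_mov = organs_mov),
       spec = spec)
}

#' Tumor field specification
#'
#' Models the size distribution reported for GFP-labeled metastases
#' (diameters from 0.1 to 6 mm, most lesions in one organ): spheres with
#' uniformly sampled diameters placed inside the body mask. Sub-voxel
#' spheres may rasterise to nothing at coarse spacing; tests choose ranges
#' representable on their grid.
#'
#' @param seed RNG seed.
#' @param n_tumors count.
#' @param diameter_range mm range (uniform).
#' @param organ_weights optional placement weights over organ masks.
#' @return A `cryo_tumorspec` list.
#' @export
TumorSpec <- function(seed = 1L, n_tumors = 30L, diameter_range = c(0.1, 6),
                      organ_weights = NULL) {
  if (any(diameter_range <= 0)) stop("diameters must be positive")
  structure(list(seed = as.integer(seed), n_tumors = as.integer(n_tumors),
                 diameter_range = diameter_range,
                 organ_weights = organ_weights), class = "cryo_tumorspec")
}

#' Place spherical tumors with known ground truth
#'
#' @param body a [BinaryMask()] (or list of organ masks when
#'   `spec$organ_weights` is given; the body mask is then their union).
#' @param spec a [TumorSpec()].
#' @return list with `labels` (integer label [Volume()]), and `records`
#'   data.frame: label, true centre (mm), true diameter (mm).
#' @export
make_tumor_field <- function(body, spec = TumorSpec()) {
  set.seed(spec$seed)
  organs <- NULL
  if (!is.null(spec$organ_weights)) {
    organs <- body
    u <- organs[[1]]$data
    for (o in organs[-1]) u <- u | o$data
    body <- BinaryMask(u, organs[[1]]$spacing, organs[[1]]$origin)
  }
  stopifnot_mask(body)
  sh <- vol_shape(body); sp <- body$spacing
  labels <- array(0L, sh)
  recs <- NULL
  if (spec$n_tumors > 0) {
    for (i in seq_len(spec$n_tumors)) {
      pool <- if (is.null(organs)) body else
        organs[[sample(length(organs), 1, prob = spec$organ_weights)]]
      fg <- which(pool$data)
      diam <- stats::runif(1, spec$diameter_range[1], spec$diameter_range[2])
      placed <- FALSE
      for (try in 1:100) {
        cvox <- arrayInd(sample(fg, 1), sh) - 1L
        cen <- as.numeric(cvox) * sp + pool$origin
        r <- diam / 2
        marg <- 1.5 * max(sp)    # keep components 26-disconnected
        lo <- pmax(floor((cen - r - marg - pool$origin) / sp), 0)
        hi <- pmin(ceiling((cen + r + marg - pool$origin) / sp), sh - 1)
        if (any(lo > hi)) { sel <- matrix(nrow = 0, ncol = 3); wide <- sel } else {
          sub <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
          d2 <- colSums((t(sub) * sp - cen + pool$origin)^2)
          sel <- sub[d2 <= r^2, , drop = FALSE]
          wide <- sub[d2 <= (r + marg)^2, , drop = FALSE]
        }
        if (nrow(wide) > 0 && any(labels[wide + 1L] != 0)) next
        if (nrow(sel) > 0) labels[sel + 1L] <- i
        recs <- rbind(recs, data.frame(label = i, x_mm = cen[1], y_mm = cen[2],
                                       z_mm = cen[3], diameter_mm = diam))
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place tumor ", i, " without overlap")
    }
  }
  list(labels = Volume(labels, sp, body$origin),
       records = if (is.null(recs)) data.frame(label = integer(),
                                               x_mm = numeric(),
                                               y_mm = numeric(),
                                               z_mm = numeric(),
                                               diameter_mm = numeric())
                 else recs)
}

#' Generate a 2D blockface/histology phantom pair with ground truth
#'
#' Shared 2D anatomy (soft ellipses, curves and smooth texture); the
#' histology variant is observed through a truth similarity + optional
#' smooth FFD, gains fine cellular speckle and a stain-like monotone
#' intensity remap.
#'
#' @param seed RNG seed.
#' @param shape pixel pair.
#' @param spacing mm per pixel.
#' @param tx,ty,theta,scale truth similarity parameters (mm, degrees).
#' @param warp_amplitude_px peak truth FFD displacement (pixels).
#' @param warp_grid_px truth FFD lattice spacing (pixels).
#' @param noise_sd additive noise.
#' @param n_landmarks paired ground-truth landmarks.
#' @return list with `blockface`, `histology` ([Image2D()]s), `truth`
#'   (`sim`, `ffd`), and `landmarks` (`ref`, `mov` matrices in mm).
#' @export
make_histology_pair <- function(seed = 1L, shape = c(160L, 160L),
                                spacing = 0.02, tx = 0, ty = 0, theta = 0,
                                scale = 1, warp_amplitude_px = 0,
                                warp_grid_px = 16L, noise_sd = 2,
                                n_landmarks = 20L) {
  set.seed(seed)
  sh <- as.integer(shape)
  ext <- (sh - 1) * spacing
  ctr <- ext / 2
  # anatomy closure over physical mm points
  # soft ellipses + band-limited texture: edge-rich but smooth anatomy
  nell <- 6L
  ells <- lapply(seq_len(nell), function(k) list(
    cen = ctr + stats::runif(2, -0.3, 0.3) * ext,
    ax = stats::runif(2, 0.08, 0.22) * ext,
    int = stats::runif(1, 60, 220)))
  tex_step <- 5L
  tex_dim <- sh %/% tex_step + 2L
  tex <- matrix(stats::rnorm(prod(tex_dim), 0, 12), tex_dim[1], tex_dim[2])
  anat <- function(pts) {
    pts <- matrix(pts, ncol = 2)
    body <- 1 / (1 + exp((((pts[, 1] - ctr[1]) / (0.45 * ext[1]))^2 +
                          ((pts[, 2] - ctr[2]) / (0.45 * ext[2]))^2 - 1) * 14))
    v <- 30 * body
    for (e in ells) {
      d2 <- ((pts[, 1] - e$cen[1]) / e$ax[1])^2 + ((pts[, 2] - e$cen[2]) / e$ax[2])^2
      v <- v + (e$int - 30) / (1 + exp((d2 - 1) * 14)) * body
    }
    v + sample_bilinear2d(tex, pts / (spacing * tex_step)) * body
  }
  grid <- cbind(rep(0:(sh[1] - 1), sh[2]), rep(0:(sh[2] - 1), each = sh[1]))
  pts <- grid * spacing
  block_v <- anat(pts)
  blockface <- Image2D(matrix(pmin(pmax(block_v + stats::rnorm(length(block_v), 0, noise_sd), 0), 255), sh[1], sh[2]),
                       spacing)
  sim <- Similarity2D(tx, ty, theta, scale, center = ctr)
  ffd <- FFD2D(grid_spacing = warp_grid_px, shape = sh, spacing = spacing)
  if (warp_amplitude_px > 0) {
    cdim <- dim(ffd$coef)
    cf <- array(stats::rnorm(prod(cdim)), cdim)
    probe <- ffd2d_disp(cf, warp_grid_px, grid)
    peak <- max(sqrt(rowSums(probe^2)))
    ffd$coef <- cf * (warp_amplitude_px / peak) * spacing
  }
  # histology(y) = remap(anat(T^-1(y))), T(x) = sim(x + u(x))
  z <- sim2d_apply(sim2d_invert(sim), pts)
  clamp2 <- function(p) {
    p[, 1] <- pmin(pmax(p[, 1], -0.2 * ext[1]), 1.2 * ext[1])
    p[, 2] <- pmin(pmax(p[, 2], -0.2 * ext[2]), 1.2 * ext[2])
    p
  }
  x <- clamp2(z)
  for (i in 1:20)
    x <- clamp2(z - ffd2d_disp(ffd$coef / spacing, warp_grid_px,
                               x / spacing) * spacing)
  hv <- anat(x)
  hv <- 255 * (pmax(hv, 0) / 255)^0.6          # stain-like remap
  # cellular speckle: small bright dots
  nd <- round(prod(sh) * 0.02)
  dots <- cbind(sample(sh[1], nd, TRUE), sample(sh[2], nd, TRUE))
  hmat <- matrix(hv, sh[1], sh[2])
  hmat[dots] <- pmin(hmat[dots] + stats::runif(nd, 30, 90), 255)
  hmat <- hmat + matrix(stats::rnorm(prod(sh), 0, noise_sd), sh[1], sh[2])
  histology <- Image2D(pmin(pmax(hmat, 0), 255), spacing)
  # landmarks inside the body
  lm <- cbind(stats::runif(n_landmarks, 0.25, 0.75) * ext[1],
              stats::runif(n_landmarks, 0.25, 0.75) * ext[2])
  lm_mov <- sim2d_apply(sim, lm + ffd2d_disp(ffd$coef / spacing, warp_grid_px,
                                             lm / spacing) * spacing)
  list(blockface = blockface, histology = histology,
       truth = list(sim = sim, ffd = ffd),
       landmarks = list(ref = lm, mov = lm_mov))
}

#' Generate a before/after-freezing CT phantom pair
#'
#' Organs are ellipsoids at baseline Hounsfield values; the post-freezing
#' volume recomputes each organ's HU from its density scaled by the
#' requested volume factor (mass conservation: `HU' = (1000 + HU)/factor -
#' 1000`), then adds Gaussian HU noise to both volumes.
#'
#' @param seed RNG seed.
#' @param shape voxel triple.
#' @param spacing mm.
#' @param organ_hu named baseline HU per organ.
#' @param volume_factors named volume ratios `V_after / V_before` per organ.
#' @param noise_sd HU noise standard deviation.
#' @return list with `before`, `after` ([Volume()]s in HU), `rois` (named
#'   [BinaryMask()]s eroded inside each organ), and `truth_percent` (named
#'   true percent volume changes).
#' @export
make_ct_freeze_pair <- function(seed = 1L, shape = c(64L, 48L, 48L),
                                spacing = 0.2,
                                organ_hu = c(liver = 55, kidney = 40,
                                             brain = 35),
                                volume_factors = c(liver = 1.083,
                                                   kidney = 1.095,
                                                   brain = 1.04),
                                noise_sd = 15) {
  if (any(volume_factors <= 0)) stop("volume factors must be positive")
  set.seed(seed)
  sh <- as.integer(shape); sp <- rep(spacing, length.out = 3)
  ext <- (sh - 1) * sp; ctr <- ext / 2
  grid <- as.matrix(expand.grid(0:(sh[1] - 1), 0:(sh[2] - 1), 0:(sh[3] - 1)))
  pts <- sweep(grid, 2, sp, "*")
  before <- array(-1000, sh)      # air
  after <- array(-1000, sh)
  # soft-tissue body at ~20 HU
  bodysel <- ((pts[, 1] - ctr[1]) / (0.45 * ext[1]))^2 +
             ((pts[, 2] - ctr[2]) / (0.42 * ext[2]))^2 +
             ((pts[, 3] - ctr[3]) / (0.42 * ext[3]))^2 <= 1
  before[bodysel] <- 20
  after[bodysel] <- (1000 + 20) / 1.05 - 1000   # bulk tissue expands a little
  rois <- list()
  orgnames <- names(organ_hu)
  for (k in seq_along(orgnames)) {
    nm <- orgnames[k]
    cen <- c(ext[1] * (k - 0.5) / length(orgnames),
             ctr[2] + stats::runif(1, -0.1, 0.1) * ext[2],
             ctr[3] + stats::runif(1, -0.1, 0.1) * ext[3])
    ax <- c(ext[1] / length(orgnames) * 0.42, 0.28 * ext[2], 0.28 * ext[3])
    d2 <- ((pts[, 1] - cen[1]) / ax[1])^2 + ((pts[, 2] - cen[2]) / ax[2])^2 +
          ((pts[, 3] - cen[3]) / ax[3])^2
    sel <- d2 <= 1
    before[sel] <- organ_hu[[nm]]
    after[sel] <- (1000 + organ_hu[[nm]]) / volume_factors[[nm]] - 1000
    rois[[nm]] <- BinaryMask(array(d2 <= 0.6, sh), sp)   # interior ROI
  }
  before <- before + array(stats::rnorm(prod(sh), 0, noise_sd), sh)
  after <- after + array(stats::rnorm(prod(sh), 0, noise_sd), sh)
  list(before = Volume(before, sp), after = Volume(after, sp), rois = rois,
       truth_percent = 100 * (volume_factors - 1))
}
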