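#' Checkerboard QC view of two co-registered images
#'
#' Alternating square tiles from `a` and `b`, tile edges aligned to the
#' image origin. For 3D inputs an orthogonal plane and slice index select
#' the 2D view. Aligned anatomy shows features continuing across tile
#' borders.
#'
#' @param a,b co-registered [Volume()]s or [Image2D()]s on a common grid.
#' @param tile_mm tile edge length in mm (>= one pixel).
#' @param plane for volumes: `"axial"` (xy), `"coronal"` (xz) or
#'   `"sagittal"` (yz).
#' @param index 0-based slice index along the remaining axis (default middle
#'   slice).
#' @return An [Image2D()].
#' @export
checkerboard <- function(a, b, tile_mm, plane = c("axial", "coronal", "sagittal"),
                         index = NULL) {
  if (is_volume(a)) {
    plane <- match.arg(plane)
    ax <- switch(plane, axial = 3L, coronal = 2L, sagittal = 1L)
    if (is.null(index)) index <- (vol_shape(a)[ax] - 1L) %/% 2L
    sl <- function(v) {
      switch(plane,
             axial = v$data[, , index + 1L],
             coronal = v$data[, index + 1L, ],
             sagittal = v$data[index + 1L, , ])
    }
    sp_axes <- setdiff(1:3, ax)
    if (abs(diff(a$spacing[sp_axes])) > 1e-9)
      warning("checkerboard plane has anisotropic pixels; using first axis spacing")
    ia <- Image2D(sl(a), a$spacing[sp_axes[1]])
    ib <- Image2D(sl(b), a$spacing[sp_axes[1]])
    return(checkerboard(ia, ib, tile_mm))
  }
  if (!identical(dim(a$data), dim(b$data))) stop("images must share a grid")
  tile_px <- floor(tile_mm / a$spacing)
  if (tile_px < 1) stop("tile smaller than one pixel")
  sh <- dim(a$data)[1:2]
  ti <- (0:(sh[1] - 1)) %/% tile_px
  tj <- (0:(sh[2] - 1)) %/% tile_px
  pick_b <- outer(ti, tj, "+") %% 2 == 1
  if (img_is_color(a)) {
    out <- a$data
    for (ch in 1:3) {
      oc <- out[, , ch]; bc <- b$data[, , ch]
      oc[pick_b] <- bc[pick_b]
      out[, , ch] <- oc
    }
  } else {
    out <- a$data
    out[pick_b] <- b$data[pick_b]
  }
  Image2D(out, a$spacing)
}

#' Label tumor-like connected components above a threshold
#'
#' 26-connected components of `channel >= threshold`; components smaller
#' than `min_voxels` are discarded. Geometry is physical: centroids in mm,
#' volumes in mm^3, and the equivalent spherical diameter
#' `(6 V / pi)^(1/3)`.
#'
#' @param channel scalar [Volume()] (e.g. a GFP channel).
#' @param threshold intensity cutoff (the platform's GFP segmentation was
#'   interactive, so the cutoff is user-supplied).
#' @param min_voxels minimum component size in voxels.
#' @return data.frame with label, centroid (mm), n_voxels, volume_mm3,
#'   equivalent_diameter_mm.
#' @export
label_tumors <- function(channel, threshold, min_voxels = 1L) {
  sh <- vol_shape(channel)
  lab <- label_components_cpp(channel$data >= threshold, as.integer(sh))
  if (max(lab) == 0L)
    return(data.frame(label = integer(), x_mm = numeric(), y_mm = numeric(),
                      z_mm = numeric(), n_voxels = integer(),
                      volume_mm3 = numeric(),
                      equivalent_diameter_mm = numeric()))
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= min_voxels)
  vx <- prod(channel$spacing)
  out <- lapply(seq_along(keep), function(i) {
    k <- keep[i]
    idx <- which(lab == k, arr.ind = TRUE) - 1L
    cen <- colMeans(idx) * channel$spacing + channel$origin
    vol <- counts[k] * vx
    # label keeps the id used in the attached label array, so downstream
    # lookups stay valid when min_voxels filtered some components out
    data.frame(label = k, x_mm = cen[1], y_mm = cen[2], z_mm = cen[3],
               n_voxels = counts[k], volume_mm3 = vol,
               equivalent_diameter_mm = (6 * vol / pi)^(1 / 3))
  })
  out <- do.call(rbind, out)
  attr(out, "labels") <- lab
  out
}

#' Classify tumor records by equivalent diameter
#'
#' Size classes follow the platform's colour coding: small `< 0.5 mm`,
#' medium `0.5-2 mm` (inclusive on both ends), large `> 2 mm`.
#'
#' @param records data.frame with an `equivalent_diameter_mm` (or
#'   `diameter_mm`) column.
#' @param thresholds the two class boundaries in mm.
#' @return list with `counts` (named small/medium/large) and `records` with
#'   an added `size_class` factor.
#' @export
classify_by_size <- function(records, thresholds = c(0.5, 2)) {
  d <- records$equivalent_diameter_mm
  if (is.null(d)) d <- records$diameter_mm
  if (is.null(d)) stop("records need an equivalent_diameter_mm column")
  cls <- ifelse(d < thresholds[1], "small",
                ifelse(d <= thresholds[2], "medium", "large"))
  cls <- factor(cls, levels = c("small", "medium", "large"))
  records$size_class <- cls
  list(counts = table(cls), records = records)
}

#' A study of co-registered channels
#'
#' Binds a reference volume to any number of channel volumes, each with the
#' transform chain (affine and/or FFD) that maps reference physical
#' coordinates into that channel's frame; `NULL` transforms mean the channel
#' is already in the reference frame (as concurrently acquired fluorescence
#' channels are).
#'
#' @param reference the reference [Volume()].
#' @param channels named list; each element a list with `volume` and
#'   optional `affine`, `ffd`.
#' @return A `cryo_study` object.
#' @export
LinkedStudy <- function(reference, channels) {
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be a named list")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is_volume(ch$volume)) stop("channel ", nm, " needs a volume")
  }
  structure(list(reference = reference, channels = channels),
            class = "cryo_study")
}

#' Interpolated patch lookup across all channels of a study
#'
#' Maps a reference-frame point through each channel's transform chain and
#' extracts an interpolated cubic patch centred there (the programmatic
#' counterpart of linked multiplanar inspection). Channels whose mapped
#' patch lies outside their volume are returned with a validity mask;
#' a channel entirely out of domain is flagged missing.
#'
#' @param study a [LinkedStudy()].
#' @param point reference-frame mm triple.
#' @param patch_mm patch edge length in mm.
#' @param n_samples samples per patch edge.
#' @return named list per channel: `patch` (3D array, `NA` outside),
#'   `valid` (logical array), `center_value`, `missing`.
#' @export
linked_lookup <- function(study, point, patch_mm = 1, n_samples = 7L) {
  point <- as.numeric(point)
  ref <- study$reference
  inref <- all(point >= ref$origin) &&
    all(point <= ref$origin + (vol_shape(ref) - 1) * ref$spacing)
  if (!inref) stop("point lies outside the reference domain")
  offs <- seq(-patch_mm / 2, patch_mm / 2, length.out = n_samples)
  grid <- as.matrix(expand.grid(offs, offs, offs))
  out <- list()
  for (nm in names(study$channels)) {
    ch <- study$channels[[nm]]
    pts <- sweep(grid, 2, point, "+")
    pts <- transform_points(pts, affine = ch$affine, ffd = ch$ffd)
    vox <- phys_to_voxel(ch$volume, pts)
    vals <- trilinear_sample_cpp(as.numeric(ch$volume$data),
                                 as.integer(vol_shape(ch$volume)), vox,
                                 NA_real_)
    patch <- array(vals, rep(n_samples, 3))
    valid <- !is.na(patch)
    out[[nm]] <- list(patch = patch, valid = valid,
                      center_value = patch[(n_samples + 1) / 2,
                                           (n_samples + 1) / 2,
                                           (n_samples + 1) / 2],
                      missing = !any(valid))
  }
  out
}

#' Per-tumor signal report across registered channels
#'
#' For each tumor component, samples every channel over the component's
#' voxels (optionally dilated by a margin) in the reference frame and
#' reports mean and max signal plus a detection flag (mean above the
#' channel's threshold). Each metastasis becomes its own small experiment.
#'
#' @param study a [LinkedStudy()].
#' @param records tumor table from [label_tumors()] (needs the `"labels"`
#'   attribute or a `labels` argument).
#' @param thresholds named per-channel detection thresholds.
#' @param labels optional integer label [Volume()] overriding the attribute.
#' @param dilate_mm margin added around each component.
#' @return data.frame: one row per tumor, columns
#'   `<channel>_mean`, `<channel>_max`, `<channel>_detected`.
#' @export
per_tumor_signal_report <- function(study, records, thresholds,
                                    labels = NULL, dilate_mm = 0) {
  lab <- if (!is.null(labels)) labels$data else attr(records, "labels")
  if (is.null(lab)) stop("need a label volume (labels argument or attribute)")
  ref <- study$reference
  out <- records
  for (nm in names(study$channels)) {
    ch <- study$channels[[nm]]
    means <- maxs <- numeric(nrow(records))
    for (i in seq_len(nrow(records))) {
      idx <- which(lab == records$label[i], arr.ind = TRUE) - 1L
      pts <- voxel_to_phys(ref, idx)
      if (dilate_mm > 0) {
        extra <- as.matrix(expand.grid(c(-dilate_mm, 0, dilate_mm),
                                       c(-dilate_mm, 0, dilate_mm),
                                       c(-dilate_mm, 0, dilate_mm)))
        pts <- do.call(rbind, lapply(seq_len(nrow(extra)), function(r)
          sweep(pts, 2, extra[r, ], "+")))
      }
      pts <- transform_points(pts, affine = ch$affine, ffd = ch$ffd)
      vox <- phys_to_voxel(ch$volume, pts)
      vals <- trilinear_sample_cpp(as.numeric(ch$volume$data),
                                   as.integer(vol_shape(ch$volume)), vox,
                                   NA_real_)
      vals <- vals[!is.na(vals)]
      means[i] <- if (length(vals)) mean(vals) else NA_real_
      maxs[i] <- if (length(vals)) max(vals) else NA_real_
    }
    out[[paste0(nm, "_mean")]] <- means
    out[[paste0(nm, "_max")]] <- maxs
    out[[paste0(nm, "_detected")]] <- !is.na(means) & means >= thresholds[[nm]]
  }
  out
}
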