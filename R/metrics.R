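#' Labeled 3D landmark set
#'
#' @param points n x 3 matrix of physical points (mm).
#' @param labels character/integer identifiers, one per point.
#' @return A `cryo_landmarks` object.
#' @export
LandmarkSet <- function(points, labels = NULL) {
  points <- rbind_points(points)
  dimnames(points) <- NULL
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(points)))
  if (length(labels) != nrow(points)) stop("one label per point required")
  structure(list(points = points, labels = as.character(labels)),
            class = "cryo_landmarks")
}

#' Read/write landmark CSV (columns label,x_mm,y_mm,z_mm)
#' @param path CSV path.
#' @return A [LandmarkSet()].
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  LandmarkSet(as.matrix(d[, c("x_mm", "y_mm", "z_mm")]), d$label)
}

#' @rdname read_landmarks
#' @param lm a [LandmarkSet()].
#' @export
write_landmarks <- function(lm, path) {
  utils::write.csv(data.frame(label = lm$labels, x_mm = lm$points[, 1],
                              y_mm = lm$points[, 2], z_mm = lm$points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Percent volume difference of two masks
#'
#' `VD = 2 | |A| - |B| | / (|A| + |B|)` with volumes in physical mm^3;
#' reported as a fraction (multiply by 100 for percent). Depends only on the
#' two volumes, not their overlap.
#'
#' @param a,b [BinaryMask()]s, both nonempty.
#' @return nonnegative fraction.
#' @export
volume_difference <- function(a, b) {
  stopifnot_mask(a); stopifnot_mask(b)
  va <- sum(a$data) * mask_voxel_volume(a)
  vb <- sum(b$data) * mask_voxel_volume(b)
  2 * abs(va - vb) / (va + vb)
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` on a common grid.
#'
#' @param a,b [BinaryMask()]s on the same grid.
#' @return fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot_mask(a, require_fg = FALSE); stopifnot_mask(b, require_fg = FALSE)
  if (!identical(vol_shape(a), vol_shape(b))) stop("masks must share a grid")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(a$data & b$data) / (na + nb)
}

#' Boundary voxels of a mask as physical points
#'
#' A foreground voxel is a boundary voxel when at least one of its
#' six-connected neighbours is background (volume faces count as background).
#' Points are voxel centers in mm.
#'
#' @param m a [BinaryMask()].
#' @return n x 3 matrix of mm points.
#' @export
mask_boundary_points <- function(m) {
  stopifnot_mask(m)
  d <- m$data
  sh <- dim(d)
  pad <- array(FALSE, sh + 2L)
  pad[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)] <- d
  core <- pad[2:(sh[1] + 1), 2:(sh[2] + 1), 2:(sh[3] + 1)]
  nb6 <- pad[1:sh[1], 2:(sh[2] + 1), 2:(sh[3] + 1)] &
         pad[3:(sh[1] + 2), 2:(sh[2] + 1), 2:(sh[3] + 1)] &
         pad[2:(sh[1] + 1), 1:sh[2], 2:(sh[3] + 1)] &
         pad[2:(sh[1] + 1), 3:(sh[2] + 2), 2:(sh[3] + 1)] &
         pad[2:(sh[1] + 1), 2:(sh[2] + 1), 1:sh[3]] &
         pad[2:(sh[1] + 1), 2:(sh[2] + 1), 3:(sh[3] + 2)]
  boundary <- core & !nb6
  idx <- which(boundary, arr.ind = TRUE) - 1L
  voxel_to_phys(m, idx)
}

#' Symmetric mean surface distance between two masks
#'
#' Boundary voxels are extracted as point sets in mm; the directed mean
#' nearest-neighbour distance is computed in both directions and the two
#' means are averaged, so the measure is symmetric by construction.
#'
#' @param a,b nonempty [BinaryMask()]s.
#' @return mean surface distance in mm.
#' @export
mean_surface_distance <- function(a, b) {
  pa <- mask_boundary_points(a)
  pb <- mask_boundary_points(b)
  (directed_mean_nn_cpp(pa, pb) + directed_mean_nn_cpp(pb, pa)) / 2
}

#' Landmark registration error
#'
#' Euclidean distance between correspondingly labeled points. The standard
#' deviation is the population form (divide by n).
#'
#' @param a,b [LandmarkSet()]s with matching labels.
#' @return list with `mean` (mm), `sd` (mm) and per-pair `distances` (named).
#' @export
landmark_error <- function(a, b) {
  if (!setequal(a$labels, b$labels) || anyDuplicated(a$labels) ||
      anyDuplicated(b$labels))
    stop("landmark sets must carry the same unique labels")
  ord <- match(a$labels, b$labels)
  d <- sqrt(rowSums((a$points - b$points[ord, , drop = FALSE])^2))
  names(d) <- a$labels
  list(mean = mean(d), sd = sqrt(mean((d - mean(d))^2)), distances = d)
}

#' Mean and standard deviation of a scalar map over an ROI
#'
#' Voxelwise statistics (population sd) of e.g. a Jacobian-determinant map
#' within a region of interest.
#'
#' @param map scalar [Volume()].
#' @param roi nonempty [BinaryMask()] on the same grid.
#' @return list with `mean` and `sd`.
#' @export
roi_stats <- function(map, roi) {
  stopifnot_mask(roi)
  if (!identical(vol_shape(map), vol_shape(roi)))
    stop("map and roi must share a grid")
  v <- map$data[roi$data]
  list(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)))
}
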