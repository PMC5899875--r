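#' Volume: a 3D image with physical geometry
#'
#' The universal image carrier of the package: a 3D scalar array (or 4D with a
#' trailing 3-channel colour axis), a per-axis voxel size in mm and the
#' physical position of voxel (0,0,0). Voxel indices are 0-based in physical
#' mapping: the centre of voxel `(i,j,k)` sits at `origin + c(i,j,k) * spacing`
#' (node-centred convention). All transforms in the package operate in
#' physical millimetres.
#'
#' @param data numeric 3D array, or 4D array whose 4th axis has length 3
#'   (colour channels).
#' @param spacing numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin numeric length-3, physical position (mm) of voxel (0,0,0).
#' @return An object of class `cryo_volume`.
#' @examples
#' v <- Volume(array(0, c(4, 4, 4)), spacing = c(0.1, 0.1, 0.1))
#' dim(v$data)
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("data must be a 3D array or a 4D array with 3 colour channels")
  if (length(dim(data)) == 4L && dim(data)[4] != 3L)
    stop("colour volumes must have exactly 3 channels")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "cryo_volume")
}

#' @export
print.cryo_volume <- function(x, ...) {
  d <- dim(x$data)
  kind <- if (length(d) == 4L) "RGB" else "scalar"
  cat(sprintf("cryo_volume: %s %s, spacing %s mm, origin %s mm\n",
              paste(d[1:3], collapse = "x"), kind,
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  rng <- range(x$data)
  cat(sprintf("  intensity range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Test for / inspect volume objects
#' @param x,v an object / a [Volume()].
#' @return `is_volume`: logical; `vol_shape`: the 3 spatial dimensions.
#' @export
is_volume <- function(x) inherits(x, "cryo_volume")

vol_is_color <- function(v) length(dim(v$data)) == 4L

#' @rdname is_volume
#' @export
vol_shape <- function(v) dim(v$data)[1:3]

#' Physical coordinates of voxel indices
#'
#' Maps 0-based voxel indices to physical mm under the node-centred
#' convention.
#'
#' @param v a [Volume()].
#' @param idx numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional).
#' @return n x 3 matrix of physical points in mm.
#' @export
voxel_to_phys <- function(v, idx) {
  idx <- rbind_points(idx)
  sweep(sweep(idx, 2, v$spacing, "*"), 2, v$origin, "+")
}

#' Voxel indices of physical coordinates
#'
#' Inverse of [voxel_to_phys()]; returns fractional 0-based indices.
#'
#' @param v a [Volume()].
#' @param pts numeric matrix (n x 3) of physical points in mm.
#' @return n x 3 matrix of 0-based (possibly fractional) voxel indices.
#' @export
phys_to_voxel <- function(v, pts) {
  pts <- rbind_points(pts)
  sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/")
}

rbind_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  storage.mode(p) <- "double"
  p
}

#' 2D image with isotropic pixel spacing
#'
#' Carrier for blockface/histology images: a 2D scalar matrix or 3D array with
#' 3 colour channels, plus an isotropic pixel size in mm.
#'
#' @param data numeric matrix or rows x cols x 3 array.
#' @param spacing scalar mm per pixel, > 0.
#' @return An object of class `cryo_image2d`.
#' @export
Image2D <- function(data, spacing = 1) {
  if (is.matrix(data)) data <- data
  else if (is.array(data) && length(dim(data)) == 3L && dim(data)[3] == 3L) data <- data
  else stop("data must be a matrix or an rows x cols x 3 array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("spacing must be a single positive number (mm per pixel)")
  structure(list(data = data, spacing = spacing), class = "cryo_image2d")
}

#' @export
print.cryo_image2d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("cryo_image2d: %dx%d%s, %g mm/px\n", d[1], d[2],
              if (length(d) == 3L) " RGB" else "", x$spacing))
  invisible(x)
}

img_is_color <- function(im) length(dim(im$data)) == 3L

#' Binary segmentation mask
#'
#' A logical 3D array with the same geometry contract as [Volume()].
#'
#' @param data logical (or coercible) 3D array.
#' @param spacing mm triple.
#' @param origin mm triple.
#' @return An object of class `cryo_mask` (also a `cryo_volume`).
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array")
  mode(data) <- "logical"
  v <- Volume(array(data, dim(data)), spacing, origin)
  class(v) <- c("cryo_mask", class(v))
  v
}

mask_voxel_volume <- function(m) prod(m$spacing)

stopifnot_mask <- function(m, require_fg = TRUE) {
  if (!inherits(m, "cryo_mask")) stop("expected a BinaryMask")
  if (require_fg && !any(m$data)) stop("mask has no foreground voxels")
  invisible(m)
}
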