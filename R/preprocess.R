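#' Convert an RGB volume or image to grayscale
#'
#' Uses the ITU-R BT.709 luma weights `0.2126 R + 0.7152 G + 0.0722 B`. The
#' heavy green weight gives good contrast on episcopic (blockface colour)
#' images.
#'
#' @param color a 3-channel [Volume()] or [Image2D()].
#' @return scalar volume/image of the same geometry.
#' @export
rgb_to_gray <- function(color) {
  w <- c(0.2126, 0.7152, 0.0722)
  if (is_volume(color)) {
    if (!vol_is_color(color)) stop("rgb_to_gray needs a 3-channel volume")
    g <- color$data[, , , 1, drop = FALSE] * w[1] +
      color$data[, , , 2, drop = FALSE] * w[2] +
      color$data[, , , 3, drop = FALSE] * w[3]
    return(Volume(array(g, dim(color$data)[1:3]), color$spacing, color$origin))
  }
  if (inherits(color, "cryo_image2d")) {
    if (!img_is_color(color)) stop("rgb_to_gray needs a 3-channel image")
    g <- color$data[, , 1, drop = FALSE] * w[1] +
      color$data[, , 2, drop = FALSE] * w[2] +
      color$data[, , 3, drop = FALSE] * w[3]
    return(Image2D(matrix(g, dim(color$data)[1], dim(color$data)[2]),
                   color$spacing))
  }
  stop("rgb_to_gray expects a Volume or Image2D")
}

#' Intensity window for 8-bit mapping
#'
#' @param lo intensity mapped to 0.
#' @param hi intensity mapped to 255; must exceed `lo`.
#' @return A `cryo_window` object.
#' @export
WindowSpec <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("window requires lo < hi")
  structure(list(lo = lo, hi = hi), class = "cryo_window")
}

#' Linearly map an intensity window to 8-bit
#'
#' Values at or below `lo` map to 0, at or above `hi` to 255, linear in
#' between, rounded half-up to the nearest integer. Joint-histogram bins for
#' mutual information are filled well when both volumes pass through this
#' mapping first.
#'
#' @param v a scalar [Volume()] (or [Image2D()]).
#' @param w a [WindowSpec()].
#' @return volume with values in `[0, 255]`.
#' @export
window_to_byte <- function(v, w) {
  if (!inherits(w, "cryo_window")) w <- WindowSpec(w[1], w[2])
  f <- function(x) {
    y <- (x - w$lo) / (w$hi - w$lo) * 255
    floor(pmin(pmax(y, 0), 255) + 0.5)
  }
  if (is_volume(v)) Volume(f(v$data), v$spacing, v$origin)
  else if (inherits(v, "cryo_image2d")) Image2D(f(v$data), v$spacing)
  else stop("window_to_byte expects a Volume or Image2D")
}

#' Antialiasing Lanczos resampling to a target spacing
#'
#' Separable Lanczos-3 interpolation per axis; when downsampling, the kernel
#' is stretched by the spacing ratio as an antialias prefilter. Weights are
#' renormalised per output sample (constants preserved exactly) and the
#' result is clamped to the input value range to suppress negative-lobe
#' overshoot. The output grid keeps the input origin and spans the same
#' physical extent.
#'
#' @param v a scalar [Volume()].
#' @param target_spacing mm triple (or scalar, recycled).
#' @param a kernel support in taps per side.
#' @return resampled [Volume()].
#' @export
lanczos_resample <- function(v, target_spacing, a = 3) {
  if (!is_volume(v) || vol_is_color(v)) stop("lanczos_resample expects a scalar Volume")
  ts <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(!is.finite(ts)) || any(ts <= 0)) stop("target_spacing must be positive")
  shape <- vol_shape(v)
  data <- v$data
  rng <- range(v$data)
  for (axis in 1:3) {
    n_in <- shape[axis]
    extent <- (n_in - 1) * v$spacing[axis]
    n_out <- floor(extent / ts[axis] + 1e-9) + 1L
    if (n_out <= 1L) stop("resampling leaves <= 1 voxel along axis ", axis)
    ratio <- ts[axis] / v$spacing[axis]
    data <- lanczos_axis_cpp(as.numeric(data), as.integer(shape), axis - 1L,
                             as.integer(n_out), ratio, as.integer(a))
    shape[axis] <- n_out
    dim(data) <- shape
  }
  data <- pmin(pmax(data, rng[1]), rng[2])
  dim(data) <- shape
  Volume(data, spacing = ts, origin = v$origin)
}

#' Crop a volume to a voxel-index box
#'
#' The origin advances by the box offset times the spacing so physical
#' coordinates are preserved.
#'
#' @param v a [Volume()].
#' @param box list or 2x3 matrix of 0-based inclusive bounds:
#'   `rbind(c(x0,y0,z0), c(x1,y1,z1))`.
#' @return cropped [Volume()].
#' @export
crop_to_box <- function(v, box) {
  if (is.list(box)) box <- rbind(box[[1]], box[[2]])
  box <- matrix(as.integer(box), nrow = 2)
  shape <- vol_shape(v)
  if (any(box[1, ] > box[2, ])) stop("reversed box bounds")
  if (any(box[1, ] < 0) || any(box[2, ] > shape - 1L)) stop("box out of range")
  ix <- (box[1, 1]:box[2, 1]) + 1L
  iy <- (box[1, 2]:box[2, 2]) + 1L
  iz <- (box[1, 3]:box[2, 3]) + 1L
  data <- if (vol_is_color(v)) v$data[ix, iy, iz, , drop = FALSE]
          else v$data[ix, iy, iz, drop = FALSE]
  Volume(data, v$spacing, v$origin + box[1, ] * v$spacing)
}
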