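#' 3D affine transform in physical coordinates
#'
#' Maps reference physical mm coordinates to moving physical mm coordinates:
#' `y = matrix %*% x + translation`.
#'
#' @param matrix 3x3 linear part; must be invertible.
#' @param translation mm triple.
#' @return An object of class `cryo_affine`.
#' @export
AffineTransform <- function(matrix = diag(3), translation = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(3, 3)) || any(!is.finite(matrix)))
    stop("matrix must be a finite 3x3 matrix")
  if (abs(det(matrix)) < 1e-12) stop("affine matrix must be invertible")
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("translation must be a finite mm triple")
  structure(list(matrix = matrix, translation = translation),
            class = "cryo_affine")
}

#' @export
print.cryo_affine <- function(x, ...) {
  cat("cryo_affine (reference mm -> moving mm)\n")
  m <- cbind(x$matrix, x$translation)
  rownames(m) <- c("x", "y", "z")
  colnames(m) <- c("m1", "m2", "m3", "t")
  print(signif(m, 6))
  invisible(x)
}

#' Apply an affine transform to points
#' @param t a [AffineTransform()].
#' @param pts n x 3 matrix of physical points (mm).
#' @return n x 3 matrix of transformed points.
#' @export
affine_apply <- function(t, pts) {
  pts <- rbind_points(pts)
  sweep(pts %*% t(t$matrix), 2, t$translation, "+")
}

#' Compose two affine transforms: `(a %then% b)(x) = a(b(x))`
#' @param a,b [AffineTransform()]s.
#' @return their composition `a(b(x))`.
#' @export
affine_compose <- function(a, b) {
  AffineTransform(a$matrix %*% b$matrix,
                  as.numeric(a$matrix %*% b$translation) + a$translation)
}

#' Invert an affine transform
#' @param t a [AffineTransform()].
#' @return the inverse transform.
#' @export
affine_invert <- function(t) {
  mi <- solve(t$matrix)
  AffineTransform(mi, -as.numeric(mi %*% t$translation))
}

#' Write/read an affine transform as JSON
#'
#' The file stores the row-major 3x3 matrix, the translation in mm, and a
#' convention statement.
#'
#' @param t a [AffineTransform()].
#' @param path output path.
#' @return `path` (write) or an [AffineTransform()] (read).
#' @export
write_affine <- function(t, path) {
  jsonlite::write_json(list(
    matrix_row_major = as.numeric(t(t$matrix)),
    translation_mm = t$translation,
    convention = "maps reference physical mm to moving physical mm; y = M x + t"
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  AffineTransform(matrix(j$matrix_row_major, 3, 3, byrow = TRUE),
                  j$translation_mm)
}

# --- multiscale helpers ------------------------------------------------------

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian smooth (sigma voxels) then subsample by an integer factor per axis.
downsample_volume <- function(v, factor = 2L, sigma = 1) {
  if (factor == 1L) return(v)
  shape <- vol_shape(v)
  data <- as.numeric(v$data)
  k <- gaussian_kernel1d(sigma)
  for (axis in 0:2) data <- conv_axis_cpp(data, as.integer(shape), axis, k)
  dim(data) <- shape
  ix <- seq(1L, shape[1], by = factor)
  iy <- seq(1L, shape[2], by = factor)
  iz <- seq(1L, shape[3], by = factor)
  Volume(data[ix, iy, iz, drop = FALSE], v$spacing * factor, v$origin)
}

# Resample `mov` through an affine onto the grid of `ref` (trilinear,
# NA outside the moving domain unless fill given).
resample_affine <- function(mov, t, ref, fill = NA_real_) {
  warp_volume(mov, affine = t, ffd = NULL, out_grid = ref, fill = fill)
}
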