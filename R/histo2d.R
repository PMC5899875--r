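#' 2D similarity transform (translation, rotation, scale)
#'
#' Maps reference (blockface) physical mm coordinates to moving (histology)
#' mm coordinates: `y = scale * R(theta) (x - center) + center + (tx, ty)`.
#' The rotation center is stored explicitly (conventionally the image
#' center) so the three pose parameters stay well conditioned.
#'
#' @param tx,ty translation in mm.
#' @param theta rotation in degrees (counter-clockwise).
#' @param scale isotropic scale factor (> 0).
#' @param center rotation center in mm.
#' @return A `cryo_sim2d` object.
#' @export
Similarity2D <- function(tx = 0, ty = 0, theta = 0, scale = 1,
                         center = c(0, 0)) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(tx = tx, ty = ty, theta = theta, scale = scale,
                 center = as.numeric(center)), class = "cryo_sim2d")
}

#' @export
print.cryo_sim2d <- function(x, ...) {
  cat(sprintf("cryo_sim2d: t = (%.3f, %.3f) mm, theta = %.3f deg, scale = %.4f\n",
              x$tx, x$ty, x$theta, x$scale))
  invisible(x)
}

sim2d_apply <- function(s, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  th <- s$theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- matrix(s$center, nrow(pts), 2, byrow = TRUE)
  (pts - ctr) %*% t(s$scale * R) + ctr +
    matrix(c(s$tx, s$ty), nrow(pts), 2, byrow = TRUE)
}

sim2d_invert <- function(s) {
  th <- -s$theta * pi / 180
  # inverse of y = sR(x-c)+c+t  is  x = (1/s)R^T (y - c - t) + c
  Similarity2D(tx = 0, ty = 0, theta = -s$theta, scale = 1 / s$scale,
               center = s$center) -> base
  # fold the translation through: x = (1/s)R^T(y - c - t) + c
  #                                 = (1/s)R^T(y - c) + c - (1/s)R^T t
  Rt <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  base$tx <- -(Rt[1, 1] * s$tx + Rt[1, 2] * s$ty) / s$scale
  base$ty <- -(Rt[2, 1] * s$tx + Rt[2, 2] * s$ty) / s$scale
  base
}

# bilinear sampling of a matrix at fractional 0-based pixel coords (n x 2),
# edge-clamped
sample_bilinear2d <- function(img, pts) {
  n1 <- nrow(img); n2 <- ncol(img)
  x <- pmin(pmax(pts[, 1], 0), n1 - 1)
  y <- pmin(pmax(pts[, 2], 0), n2 - 1)
  x0 <- pmin(floor(x), n1 - 2); y0 <- pmin(floor(y), n2 - 2)
  fx <- x - x0; fy <- y - y0
  v00 <- img[cbind(x0 + 1, y0 + 1)]; v10 <- img[cbind(x0 + 2, y0 + 1)]
  v01 <- img[cbind(x0 + 1, y0 + 2)]; v11 <- img[cbind(x0 + 2, y0 + 2)]
  (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
}

# Gaussian smooth (sigma = 1 px) + decimate, for the 2D pyramid
downsample_image2d <- function(m, factor) {
  if (factor == 1L) return(m)
  k <- gaussian_kernel1d(1)
  kh <- length(k) %/% 2
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  for (i in seq_along(k))
    out <- out + k[i] * m[pmin(pmax(seq_len(n1) + i - kh - 1, 1), n1), ]
  m2 <- matrix(0, n1, n2)
  for (i in seq_along(k))
    m2 <- m2 + k[i] * out[, pmin(pmax(seq_len(n2) + i - kh - 1, 1), n2)]
  m2[seq(1, n1, by = factor), seq(1, n2, by = factor)]
}

disk_offsets <- function(radius) {
  g <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  g[g$dx^2 + g$dy^2 <= radius^2 + 1e-9, , drop = FALSE]
}

shift_clamped <- function(img, dx, dy) {
  n1 <- nrow(img); n2 <- ncol(img)
  ri <- pmin(pmax(seq_len(n1) + dx, 1L), n1)
  ci <- pmin(pmax(seq_len(n2) + dy, 1L), n2)
  img[ri, ci, drop = FALSE]
}

gray_erode <- function(img, off) {
  out <- img
  for (r in seq_len(nrow(off)))
    out <- pmin(out, shift_clamped(img, off$dx[r], off$dy[r]))
  out
}
gray_dilate <- function(img, off) {
  out <- img
  for (r in seq_len(nrow(off)))
    out <- pmax(out, shift_clamped(img, off$dx[r], off$dy[r]))
  out
}

#' Iterative grayscale morphological open/close filtering
#'
#' Alternates grayscale opening and closing with a disk structuring element.
#' Suppresses the fine cellular texture of histology sections that has no
#' counterpart in blockface images, so that subsequent edge maps of the two
#' modalities look alike.
#'
#' @param img scalar [Image2D()].
#' @param radius disk radius in pixels (>= 1).
#' @param n_iter number of open+close rounds.
#' @return filtered [Image2D()]; output range is bounded by the input range.
#' @export
gray_open_close <- function(img, radius = 3L, n_iter = 2L) {
  if (img_is_color(img)) stop("gray_open_close expects a scalar image")
  if (radius < 1) stop("radius must be >= 1")
  off <- disk_offsets(radius)
  d <- img$data
  for (i in seq_len(n_iter)) {
    d <- gray_dilate(gray_erode(d, off), off)  # opening
    d <- gray_erode(gray_dilate(d, off), off)  # closing
  }
  Image2D(d, img$spacing)
}

#' Sobel gradient-magnitude edge image
#'
#' @param img scalar [Image2D()].
#' @return nonnegative edge-strength [Image2D()].
#' @export
edge_magnitude <- function(img) {
  if (img_is_color(img)) stop("edge_magnitude expects a scalar image")
  d <- img$data
  sx <- (shift_clamped(d, 1, -1) + 2 * shift_clamped(d, 1, 0) + shift_clamped(d, 1, 1) -
         shift_clamped(d, -1, -1) - 2 * shift_clamped(d, -1, 0) - shift_clamped(d, -1, 1)) / 8
  sy <- (shift_clamped(d, -1, 1) + 2 * shift_clamped(d, 0, 1) + shift_clamped(d, 1, 1) -
         shift_clamped(d, -1, -1) - 2 * shift_clamped(d, 0, -1) - shift_clamped(d, 1, -1)) / 8
  Image2D(sqrt(sx^2 + sy^2), img$spacing)
}

ncc2d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa <= 1e-12 || sb <= 1e-12) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

# warp mov image onto ref grid through a similarity (pull-back, bilinear)
warp_sim2d <- function(mov, sim, ref) {
  sh <- dim(ref$data)
  grid <- cbind(rep(0:(sh[1] - 1), sh[2]), rep(0:(sh[2] - 1), each = sh[1]))
  pts_mm <- grid * ref$spacing
  q <- sim2d_apply(sim, pts_mm) / mov$spacing
  matrix(sample_bilinear2d(mov$data, q), sh[1], sh[2])
}

#' 2D global similarity registration by Nelder-Mead on edge NCC
#'
#' Maximises the normalized cross-correlation between the reference edge
#' image and the moving edge image resampled through a 4-parameter similarity
#' (translation, rotation, scale), using the Nelder-Mead simplex. Parameters
#' are scaled (pixels, degrees, scale x100) so simplex steps are comparable.
#' If the first run fails to improve on the initial pose, one restart from a
#' perturbed initialisation is attempted.
#'
#' @param ref_edges,mov_edges scalar edge [Image2D()]s (see
#'   [edge_magnitude()]).
#' @param init initial [Similarity2D()].
#' @return the optimised [Similarity2D()] with attribute `"ncc"`.
#' @export
register_similarity_2d <- function(ref_edges, mov_edges,
                                   init = NULL) {
  sh <- dim(ref_edges$data)
  ctr <- (sh - 1) / 2 * ref_edges$spacing
  if (is.null(init)) init <- Similarity2D(center = ctr)
  px <- ref_edges$spacing
  par0 <- c(init$tx / px, init$ty / px, init$theta, init$scale * 100)
  obj <- function(par) {
    s <- Similarity2D(par[1] * px, par[2] * px, par[3], par[4] / 100,
                      center = init$center)
    -ncc2d(ref_edges$data, warp_sim2d(mov_edges, s, ref_edges))
  }
  run <- function(p0) stats::optim(p0, obj, method = "Nelder-Mead",
                                   control = list(maxit = 600, reltol = 1e-8))
  fit <- run(par0)
  if (fit$value >= obj(par0) - 1e-9) {
    fit2 <- run(par0 + c(2, -2, 1, 0.5))
    if (fit2$value < fit$value) fit <- fit2
  }
  out <- Similarity2D(fit$par[1] * px, fit$par[2] * px, fit$par[3],
                      fit$par[4] / 100, center = init$center)
  attr(out, "ncc") <- -fit$value
  out
}

#' 2D free-form deformation (B-spline lattice)
#'
#' @param coef 3D array `[ncx, ncy, 2]` of control displacements in mm, or
#'   `NULL` for identity.
#' @param grid_spacing pixels between control points (>= 2).
#' @param shape image shape (pixels).
#' @param spacing mm per pixel.
#' @return A `cryo_ffd2d` object.
#' @export
FFD2D <- function(coef = NULL, grid_spacing = 8L, shape, spacing = 1) {
  gs <- as.integer(grid_spacing)
  if (gs < 2L) stop("grid_spacing must be >= 2 pixels")
  shape <- as.integer(shape)
  cdim <- (shape - 1L) %/% gs + 4L
  if (is.null(coef)) coef <- array(0, c(cdim, 2L))
  if (!identical(dim(coef), as.integer(c(cdim, 2L))))
    stop("coef shape mismatch")
  structure(list(coef = coef, grid_spacing = gs, shape = shape,
                 spacing = spacing), class = "cryo_ffd2d")
}

bspl_w2 <- function(t) cbind((1 - t)^3 / 6, (3 * t^3 - 6 * t^2 + 4) / 6,
                             (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6, t^3 / 6)
bspl_d2w2 <- function(t) cbind(1 - t, 3 * t - 2, 1 - 3 * t, t)

# displacement (px units) of a 2D lattice at arbitrary fractional px coords
ffd2d_disp <- function(coef_px, gs, pts) {
  cd <- dim(coef_px)
  ux <- numeric(nrow(pts)); uy <- numeric(nrow(pts))
  u <- pts / gs
  i1 <- pmin(pmax(floor(u[, 1]), 0), cd[1] - 4)
  i2 <- pmin(pmax(floor(u[, 2]), 0), cd[2] - 4)
  t1 <- u[, 1] - i1; t2 <- u[, 2] - i2
  w1 <- bspl_w2(t1); w2 <- bspl_w2(t2)
  for (l in 1:4) for (m in 1:4) {
    idx <- cbind(i1 + l, i2 + m)           # 1-based array positions
    w <- w1[, l] * w2[, m]
    ux <- ux + w * coef_px[, , 1][idx]
    uy <- uy + w * coef_px[, , 2][idx]
  }
  cbind(ux, uy)
}

#' 2D nonrigid refinement by B-spline FFD on edge NCC
#'
#' Multiresolution (coarse-to-fine, downsampling by 2) B-spline free-form
#' deformation maximising the edge NCC after the global similarity stage,
#' regularised by 2D bending energy. The gradient of the NCC term uses
#' central finite differences with local sufficient-statistic updates; the
#' bending term's gradient is analytic.
#'
#' @param ref_edges,mov_edges scalar edge [Image2D()]s.
#' @param init the [Similarity2D()] from the global stage (applied first).
#' @param grid_spacing control spacing in pixels at full resolution.
#' @param n_levels multiresolution levels.
#' @param w_be bending-energy weight.
#' @param max_iterations per-level iteration cap.
#' @param tolerance stop when cost improvement falls below this.
#' @return A [FFD2D()] on the reference grid with attribute `"trace"`.
#' @export
register_ffd_2d <- function(ref_edges, mov_edges, init,
                            grid_spacing = 12L, n_levels = 3L, w_be = 0.05,
                            max_iterations = 60L, tolerance = 1e-5) {
  movS <- Image2D(warp_sim2d(mov_edges, init, ref_edges), ref_edges$spacing)
  shape0 <- dim(ref_edges$data)
  coef_px <- NULL
  traces <- list()
  for (level in (n_levels - 1L):0L) {
    f <- 2L^level
    if (any(shape0 %/% f < 2L * grid_spacing)) next
    ref_l <- downsample_image2d(ref_edges$data, f)
    mov_l <- downsample_image2d(movS$data, f)
    sh <- dim(ref_l)
    cd <- (sh - 1L) %/% grid_spacing + 4L
    cf <- array(0, c(cd, 2L))
    if (!is.null(coef_px)) {
      cp <- cbind(rep((seq_len(cd[1]) - 2L) * grid_spacing, cd[2]),
                  rep((seq_len(cd[2]) - 2L) * grid_spacing, each = cd[1]))
      # previous level coords are half the scale of this one
      d <- ffd2d_disp(coef_px, grid_spacing, cp / 2) * 2
      cf[, , 1] <- matrix(d[, 1], cd[1], cd[2])
      cf[, , 2] <- matrix(d[, 2], cd[1], cd[2])
    }
    grid <- cbind(rep(0:(sh[1] - 1), sh[2]), rep(0:(sh[2] - 1), each = sh[1]))
    eval_cost <- function(cc) {
      d <- ffd2d_disp(cc, grid_spacing, grid)
      w <- matrix(sample_bilinear2d(mov_l, grid + d), sh[1], sh[2])
      be <- ffd2d_bending(cc, grid_spacing, sh)
      list(cost = -ncc2d(ref_l, w) + w_be * be$mean, warped = w, be = be)
    }
    cur <- eval_cost(cf)
    trace <- cur$cost
    for (iter in seq_len(max_iterations)) {
      g <- ffd2d_grad(ref_l, mov_l, cf, grid_spacing, sh, w_be, cur)
      gmax <- max(abs(g))
      if (gmax < 1e-10) break
      dir <- -g / gmax
      step <- 0.5
      improved <- FALSE
      while (step > 1e-3) {
        cand <- cf + step * dir
        cc <- eval_cost(cand)
        if (cc$cost < cur$cost - 1e-12) {
          gain <- cur$cost - cc$cost
          cf <- cand; cur <- cc; improved <- TRUE
          trace <- c(trace, cur$cost)
          if (gain < tolerance) improved <- FALSE
          break
        }
        step <- step / 2
      }
      if (!improved) break
    }
    traces[[as.character(level)]] <- trace
    coef_px <- cf
  }
  if (is.null(coef_px)) stop("image too small for the requested pyramid")
  out <- FFD2D(coef_px * ref_edges$spacing, grid_spacing, shape0,
               ref_edges$spacing)
  attr(out, "trace") <- traces
  out
}

# mean 2D bending energy (px units) + cached second-derivative fields
ffd2d_bending <- function(coef_px, gs, sh) {
  grid <- cbind(rep(0:(sh[1] - 1), sh[2]), rep(0:(sh[2] - 1), each = sh[1]))
  u <- grid / gs
  i1 <- pmin(pmax(floor(u[, 1]), 0), dim(coef_px)[1] - 4)
  i2 <- pmin(pmax(floor(u[, 2]), 0), dim(coef_px)[2] - 4)
  t1 <- u[, 1] - i1; t2 <- u[, 2] - i2
  w1 <- bspl_w2(t1); w2 <- bspl_w2(t2)
  # derivative bases (per px)
  d1 <- cbind(-(1 - t1)^2 / 2, (3 * t1^2 - 4 * t1) / 2,
              (-3 * t1^2 + 2 * t1 + 1) / 2, t1^2 / 2) / gs
  d2 <- cbind(-(1 - t2)^2 / 2, (3 * t2^2 - 4 * t2) / 2,
              (-3 * t2^2 + 2 * t2 + 1) / 2, t2^2 / 2) / gs
  h1 <- bspl_d2w2(t1) / gs^2
  h2 <- bspl_d2w2(t2) / gs^2
  n <- nrow(grid)
  dxx <- matrix(0, n, 2); dyy <- matrix(0, n, 2); dxy <- matrix(0, n, 2)
  for (l in 1:4) for (m in 1:4) {
    idx <- cbind(i1 + l, i2 + m)
    for (k in 1:2) {
      c <- coef_px[, , k][idx]
      dxx[, k] <- dxx[, k] + h1[, l] * w2[, m] * c
      dyy[, k] <- dyy[, k] + w1[, l] * h2[, m] * c
      dxy[, k] <- dxy[, k] + d1[, l] * d2[, m] * c
    }
  }
  tot <- sum(dxx^2) + sum(dyy^2) + 2 * sum(dxy^2)
  list(mean = tot / n, sum = tot, dxx = dxx, dyy = dyy, dxy = dxy,
       i1 = i1, i2 = i2, h1 = h1, h2 = h2, w1 = w1, w2 = w2, d1 = d1, d2 = d2)
}

# gradient of (-NCC + w_be * BE_mean) wrt 2D lattice (px units)
ffd2d_grad <- function(ref_l, mov_l, cf, gs, sh, w_be, cur, eps = 0.4) {
  cd <- dim(cf)[1:2]
  n <- prod(sh)
  r <- as.numeric(ref_l)
  w <- as.numeric(cur$warped)
  rc <- r - mean(r)
  sw <- sum(w); sw2 <- sum(w * w); srw <- sum(rc * w)
  sr2 <- sum(rc * rc)
  ncc_of <- function(sw, sw2, srw) {
    varw <- sw2 - sw * sw / n
    if (varw <= 1e-12) return(0)
    srw / sqrt(sr2 * varw)   # rc already centered: sum(rc)=0
  }
  be <- cur$be
  grid <- cbind(rep(0:(sh[1] - 1), sh[2]), rep(0:(sh[2] - 1), each = sh[1]))
  u0 <- ffd2d_disp(cf, gs, grid)
  pos <- grid + u0
  g <- array(0, c(cd, 2))
  for (a1 in seq_len(cd[1])) {
    x0 <- max(0, (a1 - 4) * gs); x1 <- min(sh[1] - 1, a1 * gs - 1)
    if (x0 > x1) next
    for (a2 in seq_len(cd[2])) {
      y0 <- max(0, (a2 - 4) * gs); y1 <- min(sh[2] - 1, a2 * gs - 1)
      if (y0 > y1) next
      xs <- x0:x1
      sel <- as.vector(outer(xs + 1, y0:y1, function(i, j) i + (j) * sh[1]))
      # basis weights of this CP at the support pixels
      l1 <- a1 - floor(grid[sel, 1] / gs) - 1   # 0..3 index into tables
      l2 <- a2 - floor(grid[sel, 2] / gs) - 1
      okl <- l1 >= 0 & l1 <= 3 & l2 >= 0 & l2 <= 3
      sel <- sel[okl]; l1 <- l1[okl]; l2 <- l2[okl]
      if (!length(sel)) next
      wt <- be$w1[cbind(sel, l1 + 1)] * be$w2[cbind(sel, l2 + 1)]
      hxx <- be$h1[cbind(sel, l1 + 1)] * be$w2[cbind(sel, l2 + 1)]
      hyy <- be$w1[cbind(sel, l1 + 1)] * be$h2[cbind(sel, l2 + 1)]
      hxy <- be$d1[cbind(sel, l1 + 1)] * be$d2[cbind(sel, l2 + 1)]
      for (k in 1:2) {
        # NCC term: central FD with local updates
        pp <- pos[sel, , drop = FALSE]; pm <- pos[sel, , drop = FALSE]
        pp[, k] <- pp[, k] + eps * wt
        pm[, k] <- pm[, k] - eps * wt
        wp <- sample_bilinear2d(mov_l, pp)
        wm <- sample_bilinear2d(mov_l, pm)
        wo <- w[sel]
        nccp <- ncc_of(sw + sum(wp - wo), sw2 + sum(wp^2 - wo^2),
                       srw + sum(rc[sel] * (wp - wo)))
        nccm <- ncc_of(sw + sum(wm - wo), sw2 + sum(wm^2 - wo^2),
                       srw + sum(rc[sel] * (wm - wo)))
        gncc <- -(nccp - nccm) / (2 * eps)
        # bending term: analytic (quadratic form)
        gbe <- 2 * (sum(be$dxx[sel, k] * hxx) + sum(be$dyy[sel, k] * hyy) +
                    2 * sum(be$dxy[sel, k] * hxy)) / n
        g[a1, a2, k] <- gncc + w_be * gbe
      }
    }
  }
  g
}

#' Apply similarity + optional FFD to a 2D image in one interpolation step
#'
#' Pull-back resampling: for each output pixel the FFD displacement (defined
#' on the reference/output grid) is applied, then the similarity, and the
#' moving image is sampled once (bilinear, per channel for colour).
#'
#' @param img moving [Image2D()].
#' @param sim a [Similarity2D()] (or `NULL` for identity).
#' @param ffd optional [FFD2D()].
#' @param out_geometry list with `shape` (px) and `spacing` (mm/px);
#'   defaults to `img`'s own geometry.
#' @return resampled [Image2D()].
#' @export
apply_transform_2d <- function(img, sim = NULL, ffd = NULL,
                               out_geometry = NULL) {
  if (is.null(out_geometry))
    out_geometry <- list(shape = dim(img$data)[1:2], spacing = img$spacing)
  sh <- as.integer(out_geometry$shape)
  sp <- out_geometry$spacing
  grid <- cbind(rep(0:(sh[1] - 1), sh[2]), rep(0:(sh[2] - 1), each = sh[1]))
  pts <- grid * sp
  if (!is.null(ffd))
    pts <- pts + ffd2d_disp(ffd$coef / ffd$spacing, ffd$grid_spacing,
                            grid * sp / ffd$spacing) * ffd$spacing
  if (!is.null(sim)) pts <- sim2d_apply(sim, pts)
  q <- pts / img$spacing
  if (img_is_color(img)) {
    out <- array(0, c(sh, 3L))
    for (ch in 1:3)
      out[, , ch] <- matrix(sample_bilinear2d(img$data[, , ch], q), sh[1], sh[2])
  } else {
    out <- matrix(sample_bilinear2d(img$data, q), sh[1], sh[2])
  }
  Image2D(out, sp)
}

#' Checkerboard / edge-coincidence QC images for a registered 2D pair
#'
#' @param a,b co-registered scalar [Image2D()]s on the same grid.
#' @param tile_mm tile edge length in mm.
#' @return list with `checkerboard` ([Image2D()]) and `edge_overlay`
#'   (RGB [Image2D()]: reference-only edges red, moving-only white-on-black,
#'   coincident edges white+red).
#' @export
histo_qc <- function(a, b, tile_mm = 0.4) {
  cb <- checkerboard(a, b, tile_mm)
  ea <- edge_magnitude(a)$data; eb <- edge_magnitude(b)$data
  ta <- ea > stats::quantile(ea, 0.9); tb <- eb > stats::quantile(eb, 0.9)
  rgb <- array(0, c(dim(ea), 3))
  rgb[, , 1] <- 255 * (ta | tb)   # red: any edge
  rgb[, , 2] <- 255 * (ta & tb)   # white where they coincide
  rgb[, , 3] <- 255 * (ta & tb)
  list(checkerboard = cb, edge_overlay = Image2D(rgb, a$spacing))
}
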