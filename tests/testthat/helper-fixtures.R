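# Small fixtures shared across test files. Everything is generated in code;
# nothing is read from disk except files the tests write themselves.

fixture_textured_volume <- function(shape = c(24, 20, 20), seed = 42,
                                    noise_sd = 4) {
  set.seed(seed)
  sh <- shape
  base <- array(0, sh)
  for (i in seq_len(sh[1])) for (j in seq_len(sh[2]))
    base[i, j, ] <- 128 + 90 * sin(i / 3) * cos(j / 4) +
      20 * sin(seq_len(sh[3]) / 2.5)
  base <- base + array(rnorm(prod(sh), 0, noise_sd), sh)
  Volume(pmin(pmax(base, 0), 255), spacing = c(1, 1, 1))
}

fixture_sphere_mask <- function(shape = c(20, 20, 20), center_vox = NULL,
                                radius_vox = 6, spacing = 1) {
  if (is.null(center_vox)) center_vox <- (shape - 1) / 2
  idx <- as.matrix(expand.grid(0:(shape[1] - 1), 0:(shape[2] - 1),
                               0:(shape[3] - 1)))
  d2 <- (idx[, 1] - center_vox[1])^2 + (idx[, 2] - center_vox[2])^2 +
        (idx[, 3] - center_vox[3])^2
  BinaryMask(array(d2 <= radius_vox^2, shape),
             spacing = rep(spacing, length.out = 3))
}

fixture_box_mask <- function(shape, lo, hi, spacing = 1) {
  a <- array(FALSE, shape)
  a[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1] <- TRUE
  BinaryMask(a, spacing = rep(spacing, length.out = 3))
}

# brute-force R oracle for the symmetric mean surface distance
oracle_surface_distance <- function(a, b) {
  pa <- mask_boundary_points(a)
  pb <- mask_boundary_points(b)
  directed <- function(p, q) {
    mean(vapply(seq_len(nrow(p)), function(i)
      sqrt(min(colSums((t(q) - p[i, ])^2))), numeric(1)))
  }
  (directed(pa, pb) + directed(pb, pa)) / 2
}

# linear-reproduction FFD coefficients for a uniform scale about the origin
ffd_scale_coef <- function(t0, s) {
  cdim <- dim(t0$coef)[1:3]
  gs <- t0$grid_spacing
  coef <- array(0, c(cdim, 3))
  for (a in seq_len(cdim[1])) coef[a, , , 1] <- (s - 1) * (a - 2) * gs[1]
  for (a in seq_len(cdim[2])) coef[, a, , 2] <- (s - 1) * (a - 2) * gs[2]
  for (a in seq_len(cdim[3])) coef[, , a, 3] <- (s - 1) * (a - 2) * gs[3]
  coef
}
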