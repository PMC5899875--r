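test_that("abs_ncc is polarity-invariant, symmetric and near 0 for noise", {
  set.seed(12)
  blk <- array(runif(20^3) * 255, c(20, 20, 20))
  expect_equal(abs_ncc(blk, blk), 1)
  expect_equal(abs_ncc(blk, 255 - blk), 1)
  expect_equal(abs_ncc(blk, 3 * blk + 17), 1)       # affine intensity invariance
  expect_equal(abs_ncc(blk, -2 * blk + 40), 1)      # negative gain too
  other <- array(runif(20^3) * 255, c(20, 20, 20))
  expect_lt(abs_ncc(blk, other), 0.1)
  expect_equal(abs_ncc(blk, other), abs_ncc(other, blk))
  expect_error(abs_ncc(blk, array(5, c(20, 20, 20))), "variance")
})

test_that("block matching recovers exact shifts, including inverted contrast", {
  v <- fixture_textured_volume(c(30, 26, 26), seed = 13)
  cfg <- BlockMatchConfig(block_size = 8, search_size = 14, block_overlap = 3,
                          n_levels = 1, n_iterations = 1)
  # identical volumes: all displacements zero
  bm0 <- block_displacement_field(v, v, cfg)
  expect_equal(max(abs(bm0$displacements)), 0)
  expect_true(all(bm0$scores > 0.999))
  # translation by 2 voxels in x
  sh <- vol_shape(v)
  mov <- v
  mov$data[3:sh[1], , ] <- v$data[1:(sh[1] - 2), , ]
  bm <- block_displacement_field(v, mov, cfg)
  expect_true(all(abs(bm$displacements[, 1] - 2) < 1e-12))
  expect_equal(max(abs(bm$displacements[, 2:3])), 0)
  # contrast inversion + 3 voxels in y
  inv <- v
  inv$data[, 4:sh[2], ] <- 255 - v$data[, 1:(sh[2] - 3), ]
  bmi <- block_displacement_field(v, inv, cfg)
  disp_y <- bmi$displacements[, 2]
  expect_gt(mean(abs(disp_y - 3) < 1e-12), 0.9)   # interior blocks all agree
})

test_that("trimmed least squares matches OLS at reject 0 and resists outliers", {
  set.seed(14)
  n <- 60
  p <- cbind(runif(n, 0, 20), runif(n, 0, 15), runif(n, 0, 15))
  A <- AffineTransform(matrix(c(0.98, 0.02, 0, -0.03, 1.05, 0.01,
                                0.01, 0, 0.97), 3, 3, byrow = TRUE),
                       c(1.5, -0.7, 0.3))
  q <- affine_apply(A, p)
  matches <- list(centers = p, displacements = q - p)
  # reject 0 == ordinary least squares (normal-equations oracle)
  fit0 <- fit_transform_trimmed(matches, "affine", 0)
  X <- cbind(p, 1)
  beta <- solve(t(X) %*% X, t(X) %*% q)
  expect_equal(fit0$matrix, t(beta[1:3, ]), tolerance = 1e-10)
  expect_equal(fit0$translation, as.numeric(beta[4, ]), tolerance = 1e-10)
  # 30% outliers, reject 0.5
  q_out <- q
  bad <- sample(n, round(0.3 * n))
  q_out[bad, ] <- q_out[bad, ] + matrix(runif(3 * length(bad), -8, 8),
                                        ncol = 3)
  fit <- fit_transform_trimmed(list(centers = p, displacements = q_out - p),
                               "affine", 0.5)
  expect_lt(max(abs(fit$matrix - A$matrix)), 0.01)
  expect_lt(max(abs(fit$translation - A$translation)), 0.1)
  # consistent translation
  t_only <- fit_transform_trimmed(
    list(centers = p, displacements = matrix(rep(c(1, 2, -1), each = n), ncol = 3)),
    "affine", 0.5)
  expect_equal(t_only$matrix, diag(3), tolerance = 1e-9)
  expect_equal(t_only$translation, c(1, 2, -1), tolerance = 1e-9)
})

test_that("rigid fit recovers a pure rotation to 0.1 degree", {
  set.seed(15)
  n <- 40
  p <- cbind(runif(n, -10, 10), runif(n, -10, 10), runif(n, -10, 10))
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  q <- p %*% t(R) + matrix(rnorm(3 * n, 0, 0.01), ncol = 3)
  fit <- fit_transform_trimmed(list(centers = p, displacements = q - p),
                               "rigid", 0.2)
  ang <- atan2(fit$matrix[2, 1], fit$matrix[1, 1]) * 180 / pi
  expect_lt(abs(ang - 10), 0.1)
  # the linear part is an exact rotation
  expect_equal(t(fit$matrix) %*% fit$matrix, diag(3), tolerance = 1e-9)
  expect_equal(det(fit$matrix), 1, tolerance = 1e-9)
})

test_that("self-registration stays within a voxel; degenerate input errors", {
  v <- fixture_textured_volume(c(28, 24, 24), seed = 16)
  cfg <- BlockMatchConfig(block_size = 8, search_size = 12, n_levels = 2,
                          n_iterations = 5)
  t <- register_affine_multiscale(v, v, cfg)
  corners <- rbind(c(0, 0, 0), c(27, 23, 23))
  moved <- affine_apply(t, corners)
  expect_lt(max(abs(moved - corners)), 0.5)
  expect_lt(max(abs(t$matrix - diag(3))), 0.01)
  # coplanar centers break the affine fit
  p_flat <- cbind(runif(20, 0, 10), runif(20, 0, 10), 5)
  expect_error(fit_transform_trimmed(
    list(centers = p_flat, displacements = p_flat * 0), "affine", 0),
    "coplanar|degenerate")
})

test_that("affine transform JSON round trips", {
  t <- AffineTransform(matrix(c(1, 0.1, 0, -0.1, 0.9, 0, 0, 0, 1.1), 3, 3),
                       c(1, 2, 3))
  f <- tempfile(fileext = ".json")
  write_affine(t, f)
  t2 <- read_affine(f)
  expect_equal(t2$matrix, t$matrix)
  expect_equal(t2$translation, t$translation)
  unlink(f)
  # composition/inversion consistency
  comp <- affine_compose(t, affine_invert(t))
  expect_equal(comp$matrix, diag(3), tolerance = 1e-12)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-12)
})
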