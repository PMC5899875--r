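test_that("gray_open_close removes impulses, bounds range, keeps constants", {
  const <- Image2D(matrix(80, 20, 20), 1)
  expect_equal(gray_open_close(const, 2, 1)$data, const$data)
  imp <- Image2D(matrix(10, 20, 20), 1)
  imp$data[10, 10] <- 250
  out <- gray_open_close(imp, 2, 1)
  expect_equal(out$data[10, 10], 10)
  # boundedness on arbitrary input
  set.seed(35)
  noisy <- Image2D(matrix(runif(400) * 255, 20, 20), 1)
  f <- gray_open_close(noisy, 3, 2)
  expect_gte(min(f$data), min(noisy$data))
  expect_lte(max(f$data), max(noisy$data))
  expect_error(gray_open_close(noisy, 0), "radius")
})

test_that("morphological filtering improves edge agreement on speckled images", {
  set.seed(36)
  sh <- c(96, 96)
  xy <- cbind(rep(0:(sh[1] - 1), sh[2]), rep(0:(sh[2] - 1), each = sh[1]))
  clean <- matrix(128 + 100 / (1 + exp(-((xy[, 1] - 48)^2 / 400 +
                                         (xy[, 2] - 48)^2 / 500 - 1) * -4)),
                  sh[1], sh[2])
  speck <- clean
  nd <- 400
  dots <- cbind(sample(sh[1], nd, TRUE), sample(sh[2], nd, TRUE))
  speck[dots] <- speck[dots] + runif(nd, 60, 120)
  e_clean <- edge_magnitude(Image2D(clean, 1))$data
  e_speck <- edge_magnitude(Image2D(speck, 1))$data
  e_filt <- edge_magnitude(gray_open_close(Image2D(speck, 1), 2, 2))$data
  expect_gt(cor(as.numeric(e_filt), as.numeric(e_clean)),
            cor(as.numeric(e_speck), as.numeric(e_clean)))
})

test_that("edge_magnitude: zeros on constants, localized on steps, isotropic", {
  expect_equal(edge_magnitude(Image2D(matrix(9, 12, 12), 1))$data,
               matrix(0, 12, 12))
  step <- Image2D(cbind(matrix(0, 12, 6), matrix(100, 12, 6)), 1)
  e <- edge_magnitude(step)$data
  expect_true(all(e[, 6:7] > 0))
  expect_equal(e[, c(1:4, 9:12)], matrix(0, 12, 8))
  # 90-degree rotation commutes with the operator
  set.seed(37)
  img <- matrix(runif(20 * 20) * 255, 20, 20)
  rot <- function(m) t(m)[, nrow(m):1]
  e1 <- rot(edge_magnitude(Image2D(img, 1))$data)
  e2 <- edge_magnitude(Image2D(rot(img), 1))$data
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("similarity self-registration returns the identity pose", {
  hp <- make_histology_pair(seed = 38, shape = c(96, 96), noise_sd = 1)
  e <- edge_magnitude(hp$blockface)
  s <- register_similarity_2d(e, e)
  px <- hp$blockface$spacing
  expect_lt(abs(s$tx) / px, 0.5)
  expect_lt(abs(s$ty) / px, 0.5)
  expect_lt(abs(s$theta), 0.2)
  expect_lt(abs(s$scale - 1), 0.005)
})

test_that("apply_transform_2d: identity copy and exact integer shifts", {
  set.seed(39)
  img <- Image2D(matrix(runif(24 * 24) * 255, 24, 24), 0.5)
  out <- apply_transform_2d(img, Similarity2D())
  expect_equal(out$data, img$data)
  shift <- apply_transform_2d(img, Similarity2D(tx = 2 * 0.5))
  expect_equal(shift$data[1:22, ], img$data[3:24, ])
  # colour images resample per channel
  col <- Image2D(array(runif(24 * 24 * 3) * 255, c(24, 24, 3)), 0.5)
  outc <- apply_transform_2d(col, Similarity2D(tx = 0.5))
  expect_equal(outc$data[1:23, , 2], col$data[2:24, , 2])
})

test_that("one-step 2D resampling beats two-step against the analytic scene", {
  sh <- c(48, 48)
  xy <- cbind(rep(0:(sh[1] - 1), sh[2]), rep(0:(sh[2] - 1), each = sh[1]))
  f <- function(p) 128 + 90 * sin(p[, 1] * 1.3) * cos(p[, 2] * 1.1)
  mov <- Image2D(matrix(f(xy), sh[1], sh[2]), 1)
  sim <- Similarity2D(tx = 0.6, ty = -0.4, theta = 3, scale = 0.98,
                      center = c(23.5, 23.5))
  ffd <- FFD2D(grid_spacing = 12, shape = sh, spacing = 1)
  set.seed(40)
  ffd$coef <- array(rnorm(length(ffd$coef), 0, 0.5), dim(ffd$coef))
  geo <- list(shape = sh, spacing = 1)
  one <- apply_transform_2d(mov, sim, ffd, geo)
  two <- apply_transform_2d(apply_transform_2d(mov, sim, NULL, geo),
                            NULL, ffd, geo)
  u <- cryoreg:::ffd2d_disp(ffd$coef, 12, xy)
  truth <- f(cryoreg:::sim2d_apply(sim, xy + u))
  err1 <- mean(abs(as.numeric(one$data) - truth))
  err2 <- mean(abs(as.numeric(two$data) - truth))
  expect_lt(err1, err2)
})

test_that("register_ffd_2d returns a near-zero lattice with no distortion", {
  # genuinely zero residual distortion: identical edge images, identity init
  hp <- make_histology_pair(seed = 41, shape = c(80, 80), noise_sd = 1)
  re <- edge_magnitude(hp$blockface)
  ffd <- register_ffd_2d(re, re, Similarity2D(), grid_spacing = 10,
                         n_levels = 2, max_iterations = 15)
  expect_lt(max(abs(ffd$coef)) / hp$blockface$spacing, 0.5)
  # cost trace of the accepted steps is nonincreasing
  for (tr in attr(ffd, "trace")) expect_true(all(diff(tr) <= 1e-12))
})

test_that("histo_qc produces checkerboard and edge-overlay artifacts", {
  hp <- make_histology_pair(seed = 42, shape = c(64, 64))
  qc <- histo_qc(hp$blockface, hp$blockface, tile_mm = 0.2)
  expect_s3_class(qc$checkerboard, "cryo_image2d")
  expect_equal(dim(qc$edge_overlay$data)[3], 3)
  # identical inputs: every strong edge coincides (green==blue channel on)
  strong <- qc$edge_overlay$data[, , 1] > 0
  expect_true(all(qc$edge_overlay$data[, , 2][strong] > 0))
})
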