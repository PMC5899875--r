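test_that("volume_difference follows its closed form and ignores overlap", {
  a <- fixture_box_mask(c(12, 12, 12), c(0, 0, 0), c(5, 4, 4))   # 150 voxels
  b <- fixture_box_mask(c(12, 12, 12), c(0, 0, 0), c(4, 4, 3))   # 100 voxels
  expect_equal(volume_difference(a, b), 2 * 50 / 250)
  expect_equal(volume_difference(a, a), 0)
  # translated copy: same volume, no overlap dependence
  b2 <- fixture_box_mask(c(12, 12, 12), c(6, 6, 6), c(11, 10, 10))
  expect_equal(volume_difference(a, b2), 0)
  expect_error(volume_difference(a, BinaryMask(array(FALSE, c(2, 2, 2)))))
})

test_that("dice matches hand counts", {
  a <- fixture_box_mask(c(8, 8, 8), c(0, 0, 0), c(1, 1, 1))   # 2x2x2 cube
  b <- fixture_box_mask(c(8, 8, 8), c(1, 0, 0), c(2, 1, 1))   # overlaps in 1x2x2
  expect_equal(dice(a, b), 2 * 4 / 16)
  expect_equal(dice(a, a), 1)
  c <- fixture_box_mask(c(8, 8, 8), c(5, 5, 5), c(6, 6, 6))
  expect_equal(dice(a, c), 0)
})

test_that("mean_surface_distance: exact cases and brute-force oracle equality", {
  m <- fixture_sphere_mask(c(14, 14, 14), radius_vox = 4)
  expect_equal(mean_surface_distance(m, m), 0)
  # two parallel full-width plates d apart: every boundary voxel of one is
  # exactly d from the other (full extent, so no edge effects)
  sh <- c(10, 10, 10)
  p1 <- fixture_box_mask(sh, c(2, 0, 0), c(2, 9, 9), spacing = 0.5)
  p2 <- fixture_box_mask(sh, c(7, 0, 0), c(7, 9, 9), spacing = 0.5)
  expect_equal(mean_surface_distance(p1, p2), 5 * 0.5)
  # accelerated implementation equals the O(N^2) R oracle exactly
  set.seed(7)
  a <- fixture_sphere_mask(c(10, 10, 10), center_vox = c(4, 5, 4),
                           radius_vox = 3, spacing = 0.3)
  b <- fixture_sphere_mask(c(10, 10, 10), center_vox = c(6, 4, 5),
                           radius_vox = 2.5, spacing = 0.3)
  expect_equal(mean_surface_distance(a, b), oracle_surface_distance(a, b))
  expect_equal(mean_surface_distance(a, b), mean_surface_distance(b, a))
})

test_that("landmark_error computes Euclidean stats with population sd", {
  a <- LandmarkSet(rbind(c(0, 0, 0), c(10, 0, 0)), c("p", "q"))
  expect_equal(landmark_error(a, a)$mean, 0)
  b <- LandmarkSet(rbind(c(3, 4, 0), c(10, 0, 0)), c("p", "q"))
  le1 <- landmark_error(LandmarkSet(rbind(c(0, 0, 0)), "p"),
                        LandmarkSet(rbind(c(3, 4, 0)), "p"))
  expect_equal(le1$mean, 5)
  expect_equal(le1$sd, 0)
  # distances 1 and 3 -> mean 2, population sd 1; label order must not matter
  c1 <- LandmarkSet(rbind(c(0, 0, 0), c(0, 0, 10)), c("a", "b"))
  c2 <- LandmarkSet(rbind(c(0, 0, 13), c(1, 0, 0)), c("b", "a"))
  le <- landmark_error(c1, c2)
  expect_equal(le$mean, 2)
  expect_equal(le$sd, 1)
  expect_error(landmark_error(c1, LandmarkSet(rbind(c(0, 0, 0)), "a")), "label")
})

test_that("roi_stats reports voxelwise mean and population sd", {
  sh <- c(6, 6, 6)
  map <- array(1, sh)
  map[1:3, , ] <- 3
  roi_all <- BinaryMask(array(TRUE, sh))
  st <- roi_stats(Volume(map, c(1, 1, 1)), roi_all)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, 1)
  const <- roi_stats(Volume(array(4.2, sh), c(1, 1, 1)), roi_all)
  expect_equal(const$mean, 4.2)
  expect_equal(const$sd, 0)
  expect_error(roi_stats(Volume(map, c(1, 1, 1)),
                         BinaryMask(array(FALSE, sh))), "foreground")
})

test_that("dice and VD are invariant under a common on-grid rigid motion", {
  a <- fixture_sphere_mask(c(16, 16, 16), center_vox = c(6, 7, 8), radius_vox = 4)
  b <- fixture_sphere_mask(c(16, 16, 16), center_vox = c(8, 7, 8), radius_vox = 4)
  shift <- function(m, d) {
    arr <- array(FALSE, dim(m$data))
    arr[(1 + d):16, , ] <- m$data[1:(16 - d), , ]
    BinaryMask(arr, m$spacing)
  }
  expect_equal(dice(shift(a, 3), shift(b, 3)), dice(a, b))
  expect_equal(volume_difference(shift(a, 3), shift(b, 3)),
               volume_difference(a, b))
})

test_that("landmark CSV round trips", {
  lm <- LandmarkSet(matrix(rnorm(15), 5, 3), letters[1:5])
  f <- tempfile(fileext = ".csv")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(lm2$points, lm$points)
  expect_equal(lm2$labels, lm$labels)
  unlink(f)
})
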