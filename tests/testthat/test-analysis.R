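test_that("checkerboard: identical sources, single tile, exact 2x2 pattern", {
  set.seed(30)
  a <- Image2D(matrix(runif(64) * 255, 8, 8), spacing = 1)
  expect_equal(checkerboard(a, a, tile_mm = 3)$data, a$data)
  b <- Image2D(matrix(0, 8, 8), spacing = 1)
  expect_equal(checkerboard(a, b, tile_mm = 8)$data, a$data)   # one tile
  a0 <- Image2D(matrix(0, 8, 8), 1)
  b255 <- Image2D(matrix(255, 8, 8), 1)
  cb <- checkerboard(a0, b255, tile_mm = 4)
  expect_equal(cb$data[1:4, 1:4], matrix(0, 4, 4))
  expect_equal(cb$data[5:8, 1:4], matrix(255, 4, 4))
  expect_equal(cb$data[1:4, 5:8], matrix(255, 4, 4))
  expect_equal(cb$data[5:8, 5:8], matrix(0, 4, 4))
  expect_error(checkerboard(a, b, tile_mm = 0.5), "tile")
  # involution: swapping sources complements the pattern
  cb2 <- checkerboard(b255, a0, tile_mm = 4)
  expect_equal(cb$data + cb2$data, matrix(255, 8, 8))
  # 3D plane extraction
  v1 <- fixture_textured_volume(c(8, 8, 8), seed = 31)
  cb3 <- checkerboard(v1, v1, tile_mm = 2, plane = "coronal", index = 3)
  expect_equal(cb3$data, v1$data[, 4, ])
})

test_that("label_tumors measures discrete spheres in physical units", {
  expect_equal(nrow(label_tumors(Volume(array(0, c(8, 8, 8)), c(1, 1, 1)), 1)), 0)
  # 5-voxel-radius sphere at 0.1 mm spacing -> ~1 mm equivalent diameter
  m <- fixture_sphere_mask(c(16, 16, 16), radius_vox = 5, spacing = 0.1)
  ch <- Volume(array(as.numeric(m$data) * 200, vol_shape(m)), m$spacing)
  rec <- label_tumors(ch, 100)
  expect_equal(nrow(rec), 1)
  expect_lt(abs(rec$equivalent_diameter_mm - 1.0), 0.1)
  expect_equal(rec$n_voxels * prod(m$spacing), rec$volume_mm3)
  # centroid in mm
  expect_equal(unlist(rec[, c("x_mm", "y_mm", "z_mm")], use.names = FALSE),
               c(7.5, 7.5, 7.5) * 0.1, tolerance = 1e-9)
  # corner-touching voxels connect under 26-connectivity
  arr <- array(0, c(3, 3, 3))
  arr[1, 1, 1] <- 1; arr[2, 2, 2] <- 1
  rec2 <- label_tumors(Volume(arr, c(1, 1, 1)), 0.5)
  expect_equal(nrow(rec2), 1)
  # min_voxels filter
  arr2 <- array(0, c(6, 6, 6)); arr2[1, 1, 1] <- 1; arr2[4:5, 4:5, 4:5] <- 1
  expect_equal(nrow(label_tumors(Volume(arr2, c(1, 1, 1)), 0.5,
                                 min_voxels = 2)), 1)
})

test_that("label_tumors foreground volume equals the summed record volumes", {
  set.seed(32)
  arr <- array(runif(12^3) > 0.9, c(12, 12, 12)) * 150
  ch <- Volume(arr * 1.0, c(0.2, 0.2, 0.2))
  rec <- label_tumors(ch, 100)
  expect_equal(sum(rec$volume_mm3), sum(arr >= 100) * 0.2^3)
})

test_that("classify_by_size honors the printed class boundaries", {
  rec <- data.frame(label = 1:3, equivalent_diameter_mm = c(0.3, 1.0, 3.0))
  out <- classify_by_size(rec)
  expect_equal(as.numeric(out$counts), c(1, 1, 1))
  # boundary conventions: 0.5 and 2 are both medium
  b <- classify_by_size(data.frame(label = 1:2,
                                   equivalent_diameter_mm = c(0.5, 2)))
  expect_equal(as.numeric(b$counts), c(0, 2, 0))
  e <- classify_by_size(data.frame(label = integer(),
                                   equivalent_diameter_mm = numeric()))
  expect_equal(as.numeric(e$counts), c(0, 0, 0))
  # counts always sum to the number of records
  set.seed(33)
  r <- data.frame(label = 1:50, equivalent_diameter_mm = runif(50, 0.05, 5))
  expect_equal(sum(classify_by_size(r)$counts), 50)
})

test_that("linked_lookup resolves channels through their transforms", {
  v <- fixture_textured_volume(c(16, 16, 16), seed = 34)
  shifted <- v
  shifted$data[1:14, , ] <- v$data[3:16, , ]   # channel shifted by -2 voxels
  study <- LinkedStudy(v, list(
    same = list(volume = v),
    moved = list(volume = shifted,
                 affine = AffineTransform(translation = c(-2, 0, 0)))))
  lk <- linked_lookup(study, point = c(8, 8, 8), patch_mm = 2, n_samples = 5)
  expect_equal(lk$same$patch, lk$moved$patch, tolerance = 1e-9)
  expect_false(lk$same$missing)
  # patch past the boundary gets a validity mask, not an error
  lk2 <- linked_lookup(study, point = c(0.4, 8, 8), patch_mm = 2,
                       n_samples = 5)
  expect_true(any(!lk2$same$valid))
  expect_true(any(lk2$same$valid))
  expect_error(linked_lookup(study, point = c(-5, 8, 8)), "outside")
})

test_that("per_tumor_signal_report flags exactly the constructed signals", {
  sh <- c(20, 16, 16)
  lab <- array(0L, sh)
  lab[3:5, 3:5, 3:5] <- 1L
  lab[12:16, 8:12, 8:12] <- 2L
  base <- Volume(array(0, sh), c(0.2, 0.2, 0.2))
  agent <- base
  agent$data[12:16, 8:12, 8:12] <- 180   # signal only in tumor 2
  flat <- base                            # background-only channel
  study <- LinkedStudy(base, list(agent = list(volume = agent),
                                  blank = list(volume = flat)))
  rec <- data.frame(label = c(1L, 2L))
  rep <- per_tumor_signal_report(study, rec,
                                 thresholds = c(agent = 50, blank = 50),
                                 labels = Volume(lab, c(0.2, 0.2, 0.2)))
  expect_equal(rep$agent_detected, c(FALSE, TRUE))
  expect_equal(rep$blank_detected, c(FALSE, FALSE))
  expect_equal(rep$agent_mean[2], 180)
})
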