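test_that("NIfTI round trip preserves data, spacing and origin", {
  set.seed(1)
  v <- Volume(array(runif(4 * 4 * 4) * 255, c(4, 4, 4)),
              spacing = c(0.1, 0.1, 0.1), origin = c(1, 2, 3))
  for (ext in c(".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f, datatype = "float64")
    v2 <- read_volume(f)
    expect_equal(v2$data, v$data)
    expect_equal(v2$spacing, v$spacing)
    expect_equal(v2$origin, v$origin)
    unlink(f)
  }
  # header spacing passthrough with integer storage
  f <- tempfile(fileext = ".nii")
  write_volume(Volume(array(round(runif(8) * 255), c(2, 2, 2)),
                      spacing = c(0.1, 0.1, 0.1)), f, datatype = "uint8")
  expect_equal(read_volume(f)$spacing, c(0.1, 0.1, 0.1))
  unlink(f)
})

test_that("TIFF stacks round trip with sidecar spacing; missing spacing errors", {
  set.seed(2)
  v <- Volume(array(sample(0:255, 4 * 5 * 3, TRUE) * 1.0, c(4, 5, 3)),
              spacing = c(0.2, 0.2, 0.5))
  f <- tempfile(fileext = ".tif")
  write_volume(v, f)
  v2 <- read_volume(f)       # spacing from the sidecar written alongside
  expect_equal(v2$data, v$data)
  expect_equal(v2$spacing, v$spacing)
  # no sidecar, no override -> error
  f2 <- tempfile(fileext = ".tif")
  file.copy(f, f2)
  expect_error(read_volume(f2), "spacing")
  expect_equal(read_volume(f2, spacing_override = c(1, 1, 1))$spacing, c(1, 1, 1))
  unlink(c(f, f2, sub("\\.tif$", ".spacing.json", f)))
  # RGB volume round trip
  vc <- Volume(array(sample(0:255, 4 * 4 * 2 * 3, TRUE) * 1.0, c(4, 4, 2, 3)),
               spacing = c(1, 1, 1))
  f3 <- tempfile(fileext = ".tif")
  write_volume(vc, f3)
  expect_equal(read_volume(f3)$data, vc$data)
  unlink(c(f3, sub("\\.tif$", ".spacing.json", f3)))
})

test_that("rgb_to_gray applies the BT.709 weights and fixes gray images", {
  px <- function(r, g, b) {
    rgb_to_gray(Volume(array(c(r, g, b), c(1, 1, 1, 3)), c(1, 1, 1)))$data[1, 1, 1]
  }
  expect_equal(px(255, 255, 255), 255)
  expect_equal(px(0, 0, 0), 0)
  expect_equal(px(0, 255, 0), 182.376)
  # gray replicated into channels comes back exactly
  set.seed(3)
  g <- array(runif(3 * 3 * 2) * 255, c(3, 3, 2))
  col <- Volume(array(rep(g, 3), c(3, 3, 2, 3)), c(1, 1, 1))
  expect_equal(rgb_to_gray(col)$data, g)
  expect_error(rgb_to_gray(Volume(g, c(1, 1, 1))), "3-channel")
})

test_that("window_to_byte maps the window linearly, clamps, and is monotone", {
  vals <- c(-5, 0, 7500, 15000, 32766)
  v <- Volume(array(vals, c(5, 1, 1)), c(1, 1, 1))
  out <- window_to_byte(v, WindowSpec(0, 15000))$data
  expect_equal(as.numeric(out), c(0, 0, 128, 255, 255))
  expect_error(WindowSpec(10, 10))
  set.seed(4)
  x <- sort(runif(100, -100, 400))
  y <- window_to_byte(Volume(array(x, c(100, 1, 1)), c(1, 1, 1)),
                      WindowSpec(0, 255))$data
  expect_true(all(diff(as.numeric(y)) >= 0))
})

test_that("lanczos_resample preserves identity, constants and antialiases", {
  set.seed(5)
  v <- fixture_textured_volume(c(16, 14, 12), noise_sd = 0)
  expect_equal(lanczos_resample(v, c(1, 1, 1))$data, v$data, tolerance = 1e-10)
  cz <- lanczos_resample(Volume(array(7, c(12, 12, 12)), c(1, 1, 1)),
                         c(0.5, 0.5, 0.5))
  expect_equal(max(abs(cz$data - 7)), 0)
  expect_equal(cz$spacing, c(0.5, 0.5, 0.5))
  # above-Nyquist sinusoid is attenuated vs nearest-neighbour decimation
  n <- 64
  sig <- sin(2 * pi * 0.4 * (0:(n - 1)))   # 0.4 cycles/voxel > 0.25 out-Nyquist
  v1 <- Volume(array(rep(sig, 4 * 4), c(n, 4, 4)), c(1, 1, 1))
  lz <- lanczos_resample(v1, c(2, 1, 1))
  nn <- v1$data[seq(1, n, by = 2), , , drop = FALSE]
  p_l <- mean(abs(fft(lz$data[, 1, 1]))[-1]^2)
  p_n <- mean(abs(fft(nn[, 1, 1]))[-1]^2)
  expect_lt(p_l, 0.2 * p_n)
  # smooth volume survives down-then-up resampling
  sm <- Volume(array(rep(sin(2 * pi * 0.05 * (0:31)), 8 * 8), c(32, 8, 8)),
               c(1, 1, 1))
  down <- lanczos_resample(sm, c(2, 1, 1))
  up <- lanczos_resample(down, c(1, 1, 1))
  core <- up$data[5:27, , ]
  expect_lt(mean(abs(core - sm$data[5:27, , ])), 0.05)
})

test_that("crop_to_box preserves physical geometry and validates bounds", {
  set.seed(6)
  v <- Volume(array(runif(10 * 8 * 6), c(10, 8, 6)), spacing = c(0.1, 0.2, 0.3),
              origin = c(5, 5, 5))
  full <- crop_to_box(v, rbind(c(0, 0, 0), c(9, 7, 5)))
  expect_equal(full$data, v$data)
  expect_equal(full$origin, v$origin)
  cr <- crop_to_box(v, rbind(c(3, 1, 0), c(9, 7, 5)))
  expect_equal(cr$origin, v$origin + c(3, 1, 0) * v$spacing)
  expect_equal(cr$data[1, 1, 1], v$data[4, 2, 1])
  expect_error(crop_to_box(v, rbind(c(5, 0, 0), c(3, 7, 5))), "reversed")
  expect_error(crop_to_box(v, rbind(c(0, 0, 0), c(10, 7, 5))), "range")
})

test_that("physical center of mass survives crop + resample", {
  m <- fixture_sphere_mask(c(24, 24, 24), center_vox = c(12, 11, 13),
                           radius_vox = 5, spacing = 0.2)
  v <- Volume(array(as.numeric(m$data), vol_shape(m)), m$spacing)
  com <- function(vol) {
    idx <- which(vol$data > 0.5, arr.ind = TRUE) - 1
    w <- vol$data[vol$data > 0.5]
    colSums(voxel_to_phys(vol, idx) * w) / sum(w)
  }
  c0 <- com(v)
  cropped <- crop_to_box(v, rbind(c(3, 2, 4), c(21, 21, 21)))
  res <- lanczos_resample(cropped, c(0.3, 0.3, 0.3))
  expect_lt(max(abs(com(res) - c0)), 0.3)   # within one output voxel
})
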