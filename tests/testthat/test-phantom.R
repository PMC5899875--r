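test_that("phantom pair generators are pure functions of their spec", {
  s <- PhantomSpec(seed = 101, shape = c(24, 20, 20), rotation_deg = 3,
                   warp_amplitude_vox = 2, warp_grid_vox = 6,
                   intensity_remap = "monotone")
  a <- make_phantom_pair(s)
  b <- make_phantom_pair(s)
  expect_identical(a$ref$data, b$ref$data)
  expect_identical(a$mov$data, b$mov$data)
  expect_identical(a$landmarks$mov$points, b$landmarks$mov$points)
  expect_identical(a$truth$ffd$coef, b$truth$ffd$coef)
})

test_that("identity spec means mov equals ref exactly", {
  s <- PhantomSpec(seed = 102, shape = c(20, 16, 16), noise_sd = 0)
  ph <- make_phantom_pair(s)
  expect_equal(ph$mov$data, ph$ref$data, tolerance = 1e-9)
  expect_equal(ph$landmarks$ref$points, ph$landmarks$mov$points)
})

test_that("truth transforms are consistent and invertible", {
  s <- PhantomSpec(seed = 103, shape = c(28, 24, 24), rotation_deg = 6,
                   scale = c(0.97, 1.03, 1), translation_mm = c(0.4, -0.3, 0.2),
                   warp_amplitude_vox = 3, warp_grid_vox = 8, noise_sd = 0,
                   intensity_remap = "none")
  ph <- make_phantom_pair(s)
  # pull-back of mov through the truth transform reproduces ref (interior)
  rec <- compose_and_resample(ph$mov, ph$truth$affine, ph$truth$ffd,
                              ph$ref, fill = NA_real_)
  sel <- !is.na(rec$data)
  sel[c(1:3, 26:28), , ] <- FALSE
  expect_lt(mean(abs(rec$data[sel] - ph$ref$data[sel])), 3)
  # warp invertibility: det J > 0 everywhere
  dm <- jacobian_det_map(ph$truth$ffd)
  expect_gt(min(dm$data), 0)
  # landmark round trip through the numeric inverse
  x <- ph$landmarks$ref$points
  y <- ph$landmarks$mov$points
  x2 <- cryoreg:::phantom_invert_points(y, ph$truth$affine, ph$truth$ffd)
  expect_lt(max(sqrt(rowSums((x2 - x)^2))), 0.01)
})

test_that("truth Jacobian of a pure scaling phantom warp is the closed form", {
  dom <- list(shape = c(20L, 20L, 20L), spacing = c(1, 1, 1),
              origin = c(0, 0, 0))
  t0 <- FFDTransform(grid_spacing = 5, domain = dom)
  ts <- FFDTransform(ffd_scale_coef(t0, 1.05), 5, dom)
  dm <- jacobian_det_map(ts)
  expect_equal(dm$data, array(1.05^3, c(20, 20, 20)), tolerance = 1e-10)
})

test_that("tumor fields place spheres with accurate ground truth", {
  body <- fixture_sphere_mask(c(40, 40, 40), radius_vox = 18, spacing = 0.1)
  tf0 <- make_tumor_field(body, TumorSpec(seed = 104, n_tumors = 0))
  expect_equal(max(tf0$labels$data), 0)
  expect_equal(nrow(tf0$records), 0)
  # one 1 mm sphere at 0.1 mm spacing: labeled volume within 10% of (pi/6)
  tf1 <- make_tumor_field(body, TumorSpec(seed = 105, n_tumors = 1,
                                          diameter_range = c(1, 1)))
  vol <- sum(tf1$labels$data == 1) * 0.1^3
  expect_lt(abs(vol - pi / 6) / (pi / 6), 0.1)
  # determinism
  tf2 <- make_tumor_field(body, TumorSpec(seed = 105, n_tumors = 1,
                                          diameter_range = c(1, 1)))
  expect_identical(tf1$labels$data, tf2$labels$data)
  # several tumors: no overlap by construction (labels partition foreground)
  tf3 <- make_tumor_field(body, TumorSpec(seed = 106, n_tumors = 8,
                                          diameter_range = c(0.4, 1.2)))
  expect_equal(sort(unique(as.integer(tf3$labels$data[tf3$labels$data > 0]))),
               seq_len(8))
})

test_that("histology pair: identity truth differs only by texture/remap; seeded determinism", {
  h1 <- make_histology_pair(seed = 107, shape = c(64, 64), noise_sd = 0)
  h2 <- make_histology_pair(seed = 107, shape = c(64, 64), noise_sd = 0)
  expect_identical(h1$histology$data, h2$histology$data)
  expect_identical(h1$blockface$data, h2$blockface$data)
  # identity truth: landmarks map to themselves
  expect_equal(h1$landmarks$ref, h1$landmarks$mov)
  # forward mapping of landmarks round-trips through the truth warp
  h3 <- make_histology_pair(seed = 108, shape = c(80, 80), theta = 4,
                            scale = 1.01, tx = 0.1, ty = -0.06,
                            warp_amplitude_px = 3)
  s <- h3$truth$sim
  u <- cryoreg:::ffd2d_disp(h3$truth$ffd$coef / h3$truth$ffd$spacing,
                            h3$truth$ffd$grid_spacing,
                            h3$landmarks$ref / h3$blockface$spacing) *
       h3$truth$ffd$spacing
  fwd <- cryoreg:::sim2d_apply(s, h3$landmarks$ref + u)
  expect_lt(max(abs(fwd - h3$landmarks$mov)), 1e-9)
})

test_that("CT freeze pair: factors of 1 mean no organ change; determinism", {
  ct <- make_ct_freeze_pair(seed = 109, volume_factors = c(liver = 1,
                                                           kidney = 1,
                                                           brain = 1),
                            noise_sd = 0)
  r <- roi_volume_change(ct$before, ct$after, ct$rois$kidney)
  expect_equal(r$percent_change, 0)
  a <- make_ct_freeze_pair(seed = 110)
  b <- make_ct_freeze_pair(seed = 110)
  expect_identical(a$before$data, b$before$data)
  expect_identical(a$after$data, b$after$data)
})
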