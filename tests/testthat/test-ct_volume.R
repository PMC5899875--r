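test_that("volume_ratio follows the HU closed form and its reciprocity", {
  expect_equal(volume_ratio(50, 50), 1)
  expect_equal(volume_ratio(50, -30), 1050 / 970)
  expect_error(volume_ratio(50, -1000), "nonphysical")
  # exact reciprocity, scalars and maps
  set.seed(8)
  hu_b <- Volume(array(runif(4^3, -200, 200), c(4, 4, 4)), c(1, 1, 1))
  hu_a <- Volume(array(runif(4^3, -200, 200), c(4, 4, 4)), c(1, 1, 1))
  r1 <- volume_ratio(hu_b, hu_a)
  r2 <- volume_ratio(hu_a, hu_b)
  expect_equal(r1$data * r2$data, array(1, c(4, 4, 4)))
  # a common additive offset does change the ratio (no hidden normalisation)
  expect_false(isTRUE(all.equal(volume_ratio(50 + 100, -30 + 100),
                                volume_ratio(50, -30))))
})

test_that("roi_volume_change recovers injected density changes", {
  ct <- make_ct_freeze_pair(seed = 9, noise_sd = 5)
  for (nm in names(ct$rois)) {
    r <- roi_volume_change(ct$before, ct$after, ct$rois[[nm]])
    expect_lt(abs(r$percent_change - ct$truth_percent[[nm]]),
              2 * r$sd_percent)   # within 2x the injected noise spread
    expect_equal(r$n_excluded, 0)
  }
  # no change -> 0 +- 0 without noise
  ct0 <- make_ct_freeze_pair(seed = 9, volume_factors = c(liver = 1,
                                                          kidney = 1,
                                                          brain = 1),
                             noise_sd = 0)
  # bulk body still changes; organs do not
  r0 <- roi_volume_change(ct0$before, ct0$after, ct0$rois$liver)
  expect_equal(r0$percent_change, 0)
  expect_equal(r0$sd_percent, 0)
})

test_that("organ ordering of recovered expansions matches the generator", {
  ct <- make_ct_freeze_pair(seed = 10,
                            organ_hu = c(liver = 55, kidney = 40, brain = 35),
                            volume_factors = c(liver = 1.08, kidney = 1.09,
                                               brain = 1.04),
                            noise_sd = 8)
  got <- vapply(names(ct$rois), function(nm)
    roi_volume_change(ct$before, ct$after, ct$rois[[nm]])$percent_change,
    numeric(1))
  expect_lt(got[["liver"]], got[["kidney"]])
  expect_lt(got[["brain"]], got[["liver"]])
})

test_that("nonphysical voxels are excluded and counted, not fatal", {
  ct <- make_ct_freeze_pair(seed = 11, noise_sd = 0)
  bad <- ct$after
  idx <- which(ct$rois$liver$data)[1:5]
  bad$data[idx] <- -1500
  r <- roi_volume_change(ct$before, bad, ct$rois$liver)
  expect_equal(r$n_excluded, 5)
  expect_true(is.finite(r$percent_change))
})
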