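test_that("analytic cap volume formula hits its closed-form special cases", {
  expect_equal(ellipsoid_cap_volume(6, 6, 6, -6), 4 / 3 * pi * 216)
  expect_equal(ellipsoid_cap_volume(7, 7, 9, 0),
               0.5 * 4 / 3 * pi * 7 * 7 * 9)
  expect_equal(ellipsoid_cap_volume(7, 7, 9, 9), 0)
  expect_error(ellipsoid_cap_volume(7, 7, 9, 10), "\\[-c, c\\]")
  expect_error(ellipsoid_cap_volume(-1, 7, 9, 0), "> 0")
})

test_that("a spherical head below the cut recovers the sphere volume", {
  ph <- make_phantom(phantom_spec(a = 6, b = 6, c = 6, cut_height_mm = -6))
  expect_equal(ph$truth$head_volume_mm3, 4 / 3 * pi * 216, tolerance = 1e-12)
  seg <- segment_condylar_head(ph$volume, ph$landmarks, "R")
  expect_lt(abs(seg$volume_mm3 / ph$truth$head_volume_mm3 - 1), 0.015)
})

test_that("phantoms are bit-reproducible and robust to HU noise", {
  s1 <- make_phantom(phantom_spec(noise_sd = 30, seed = 5))
  s2 <- make_phantom(phantom_spec(noise_sd = 30, seed = 5))
  expect_identical(s1$volume$values, s2$volume$values)
  clean <- make_phantom(phantom_spec(noise_sd = 0))
  v_noisy <- segment_condylar_head(s1$volume, s1$landmarks, "R")$volume_mm3
  v_clean <- segment_condylar_head(clean$volume, clean$landmarks,
                                   "R")$volume_mm3
  expect_lt(abs(v_noisy / v_clean - 1), 0.01)
})

test_that("voxelized volume converges to the analytic truth as spacing shrinks", {
  errs <- sapply(c(1.5, 0.75, 0.375), function(s) {
    ph <- make_phantom(phantom_spec(cut_height_mm = -4.5,
                                    spacing = rep(s, 3)))
    seg <- segment_condylar_head(ph$volume, ph$landmarks, "R")
    abs(seg$volume_mm3 / ph$truth$head_volume_mm3 - 1)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("scaling one side by 1.1 scales its volume by ~1.331", {
  bp <- make_bilateral_phantom(phantom_spec(), scale_left = 1.1)
  sR <- segment_condylar_head(bp$volume, bp$landmarks, "R")
  sL <- segment_condylar_head(bp$volume, bp$landmarks, "L")
  expect_lt(abs(sL$volume_mm3 / sR$volume_mm3 / 1.331 - 1), 0.02)
  expect_equal(bp$truth$L$head_volume_mm3 / bp$truth$R$head_volume_mm3,
               1.331, tolerance = 1e-9)
})

test_that("overlapping bilateral phantoms are rejected", {
  expect_error(make_bilateral_phantom(phantom_spec(), go_halfwidth = 5),
               "overlap")
})

test_that("phantom bone stays inside the clinical HU range", {
  expect_error(phantom_spec(bone_hu = 100), "\\[226, 3071\\]")
  expect_error(phantom_spec(cut_height_mm = 20), "\\[-c, c\\]")
})
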