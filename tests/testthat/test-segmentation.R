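make_test_volume <- function(vals, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxel_volume(vals, spacing = spacing, origin = origin)
}

test_that("threshold mask is inclusive at both ends and monotone", {
  vals <- array(0, dim = c(4, 4, 4))
  vals[1, 1, 1] <- 226
  vals[2, 2, 2] <- 3071
  vals[3, 3, 3] <- 3072
  vals[4, 4, 4] <- 225.9
  vol <- make_test_volume(vals)
  m <- threshold_mask(vol, 226, 3071)
  expect_true(m[1, 1, 1] && m[2, 2, 2])
  expect_false(m[3, 3, 3] || m[4, 4, 4])
  expect_equal(sum(threshold_mask(vol, 226)), 2)
  # raising the lower bound can only shrink the mask
  set.seed(5)
  noisy <- make_test_volume(array(runif(1000, 0, 500), dim = c(10, 10, 10)))
  m226 <- threshold_mask(noisy, 226, 3071)
  m300 <- threshold_mask(noisy, 300, 3071)
  expect_true(all(m226 | !m300))
  expect_error(threshold_mask(vol, 500, 400), "exceed")
  # all-background volume gives an empty mask
  expect_equal(sum(threshold_mask(make_test_volume(array(0, c(3, 3, 3))))), 0)
})

test_that("seeded_component picks exactly the blob around the seed", {
  vals <- array(0, dim = c(20, 20, 20))
  vals[3:6, 3:6, 3:6] <- 1000      # blob A
  vals[14:17, 14:17, 14:17] <- 1000 # blob B
  vol <- make_test_volume(vals)
  mask <- threshold_mask(vol, 226, 3071)
  compA <- seeded_component(mask, c(3.5, 3.5, 3.5), vol)
  expect_equal(sum(compA), 64)
  expect_true(all(which(compA) %in% which(vals == 1000)))
  expect_true(all(arrayInd(which(compA), dim(vals))[, 1] <= 6))
  # seed just outside the blob surface falls back to the nearest true voxel
  compA2 <- seeded_component(mask, c(1.2, 4, 4), vol)
  expect_identical(compA2, compA)
  expect_error(seeded_component(array(FALSE, dim(vals)), c(4, 4, 4), vol),
               "no foreground")
  # beyond the 25 mm search radius is an error, not a silent grab
  far <- make_test_volume(vals, spacing = c(3, 3, 3))
  expect_error(seeded_component(threshold_mask(far, 226, 3071),
                                c(-20, -20, -20), far), "within 25")
})

test_that("diagonal connectivity is 26-connected", {
  vals <- array(0, dim = c(5, 5, 5))
  vals[2, 2, 2] <- 1000
  vals[3, 3, 3] <- 1000  # touches only at a corner
  vol <- make_test_volume(vals)
  comp <- seeded_component(threshold_mask(vol, 226, 3071), c(1, 1, 1), vol)
  expect_equal(sum(comp), 2)
})

test_that("clip_above_plane keeps the boundary layer (enumeration oracle)", {
  vals <- array(0, dim = c(10, 10, 10))
  vals[] <- 1000
  vol <- make_test_volume(vals)  # voxel centers at z = 0..9
  mask <- array(TRUE, dim = c(10, 10, 10))
  cut <- plane(c(0, 0, 4), c(0, 0, 1))  # through the centers of layer z = 4
  kept <- clip_above_plane(mask, cut, vol)
  # enumeration: layers 4..9 kept = 5 strictly above + 1 boundary
  expect_equal(sum(kept), 600)
  expect_true(all(kept[, , 5:10]) && !any(kept[, , 1:4]))
  # plane below everything: unchanged; above everything: empty
  expect_equal(sum(clip_above_plane(mask, plane(c(0, 0, -5), c(0, 0, 1)),
                                    vol)), 1000)
  expect_equal(sum(clip_above_plane(mask, plane(c(0, 0, 50), c(0, 0, 1)),
                                    vol)), 0)
})

test_that("segmented phantom volume matches the analytic ellipsoid oracle", {
  ph <- make_phantom(phantom_spec(a = 7, b = 7, c = 9, cut_height_mm = -9))
  seg <- segment_condylar_head(ph$volume, ph$landmarks, "R")
  analytic_full <- 4 / 3 * pi * 7 * 7 * 9
  expect_lt(abs(seg$volume_mm3 / analytic_full - 1), 0.015)
  # volume invariant: count times voxel volume
  expect_equal(seg$volume_mm3, sum(seg$mask) * voxel_size_mm3(ph$volume))
  # cut through the center: half the analytic volume
  ph0 <- make_phantom(phantom_spec(a = 7, b = 7, c = 9, cut_height_mm = 0))
  seg0 <- segment_condylar_head(ph0$volume, ph0$landmarks, "R")
  expect_lt(abs(seg0$volume_mm3 / (analytic_full / 2) - 1), 0.015)
})

test_that("head volume shrinks as the HU window narrows or the cut rises", {
  ph <- make_phantom(phantom_spec(cut_height_mm = -4.5, noise_sd = 80,
                                  seed = 9))
  v_wide <- segment_condylar_head(ph$volume, ph$landmarks, "R",
                                  hu_lo = 226)$volume_mm3
  v_narrow <- segment_condylar_head(ph$volume, ph$landmarks, "R",
                                    hu_lo = 1100)$volume_mm3
  expect_lte(v_narrow, v_wide)
  # moving the cut toward the head decreases the kept volume
  lm <- ph$landmarks
  vols <- sapply(c(-4.5, 0, 3), function(h) {
    lm2 <- unclass(lm)
    lm2["FP_R", 3] <- lm2["FP_R", 3] + (h + 4.5)
    segment_condylar_head(ph$volume, landmark_set(lm2), "R")$volume_mm3
  })
  expect_true(all(diff(vols) < 0))
})

test_that("segmentation errors are labeled with their stage", {
  ph <- make_phantom(phantom_spec())
  lm_no_fp <- landmark_set(unclass(ph$landmarks)[
    setdiff(rownames(ph$landmarks), "FP_R"), ])
  expect_error(segment_condylar_head(ph$volume, lm_no_fp, "R"),
               "\\[condylar_cut_plane\\].*FP_R")
  lm_no_po <- landmark_set(unclass(ph$landmarks)[
    setdiff(rownames(ph$landmarks), "Po_R"), ])
  expect_error(segment_condylar_head(ph$volume, lm_no_po, "R"),
               "\\[frankfurt_plane\\].*Po_R")
})

test_that("mirror-symmetric bilateral phantom segments to equal volumes", {
  bp <- make_bilateral_phantom(phantom_spec())
  segR <- segment_condylar_head(bp$volume, bp$landmarks, "R")
  segL <- segment_condylar_head(bp$volume, bp$landmarks, "L")
  expect_identical(segR$volume_mm3, segL$volume_mm3)
  expect_lt(abs(segR$volume_mm3 / bp$truth$R$head_volume_mm3 - 1), 0.015)
})
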