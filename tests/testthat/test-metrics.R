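# small hand-built fixtures: a 10x10x8 grid with two disjoint "spheres"
# and a block VOI, so every expected value can be summed by hand
fixture_grid <- function(fill = 1) {
  voxel_image(array(fill, c(10, 10, 8)), spacing = c(1, 1, 1))
}

fixture_masks <- function() {
  a <- array(FALSE, c(10, 10, 8)); a[1:3, 1:3, 1:2] <- TRUE
  b <- array(FALSE, c(10, 10, 8)); b[6:8, 6:8, 3:4] <- TRUE
  list(ra = binary_mask(a, c(1, 1, 1)), la = binary_mask(b, c(1, 1, 1)))
}

test_that("background activity is the mean over the sphere union", {
  m <- fixture_masks()
  pet <- fixture_grid(1)
  bg <- background_activity(pet, m$ra, m$la)
  expect_equal(bg$value, 1)
  expect_equal(bg$total_volume_cm3, 36 * 0.001)

  pet$values[m$ra$values] <- 1
  pet$values[m$la$values] <- 2
  bg <- background_activity(pet, m$ra, m$la)
  expect_equal(bg$value, 1.5)  # equal-size spheres
  expect_equal(unname(bg$per_sphere), c(1, 2))

  # unequal sphere sizes: brute-force sum oracle
  small <- array(FALSE, c(10, 10, 8)); small[1, 1, 5] <- TRUE
  bg2 <- background_activity(pet, binary_mask(small, c(1, 1, 1)), m$la)
  v <- pet$values
  expect_equal(bg2$value, (sum(v[small]) + sum(v[m$la$values])) / 19)
})

test_that("background activity rejects empty or overlapping spheres", {
  m <- fixture_masks()
  empty <- binary_mask(array(FALSE, c(10, 10, 8)), c(1, 1, 1))
  expect_error(background_activity(fixture_grid(), empty, m$la),
               "non-empty")
  expect_error(background_activity(fixture_grid(), m$ra, m$ra), "overlap")
})

test_that("bone threshold is the reference SUVmax, Inf when disabled", {
  pet <- fixture_grid(0)
  ref <- array(FALSE, c(10, 10, 8)); ref[1:3, 1, 1] <- TRUE
  pet$values[1:3, 1, 1] <- c(1.1, 1.3, 1.2)
  expect_equal(bone_threshold(pet, binary_mask(ref, c(1, 1, 1))), 1.3)
  expect_identical(bone_threshold(pet, NULL), Inf)
  expect_error(bone_threshold(pet, binary_mask(array(FALSE, c(10, 10, 8)),
                                               c(1, 1, 1))), "empty")
})

test_that("AMA reproduces hand-computed section and overall values", {
  m <- fixture_masks()
  pet <- fixture_grid(1)
  bg <- background_activity(pet, m$ra, m$la)  # bg = 1

  # 8 voxels with SUVs {1,1,2,2,2,2,3,3} -> intensity/cm^3 = 2.0
  sec <- array(FALSE, c(10, 10, 8)); sec[1:2, 5, 5:8] <- TRUE
  pet$values[1:2, 5, 5:8] <- c(1, 1, 2, 2, 2, 2, 3, 3)
  res <- ama(pet, list(ascending = binary_mask(sec, c(1, 1, 1))), bg)
  expect_equal(res$sections$intensity_per_cm3, 2)
  expect_equal(res$overall, 2)
  expect_equal(res$excluded, 0)

  # volume-weighted overall: 1.2 over 40 voxels, 1.0 over 20 voxels
  s1 <- array(FALSE, c(10, 10, 8)); s1[1:8, 9, 1:5] <- TRUE   # 40 voxels
  s2 <- array(FALSE, c(10, 10, 8)); s2[1:4, 10, 1:5] <- TRUE  # 20 voxels
  pet2 <- fixture_grid(1)
  pet2$values[s1] <- 1.2
  pet2$values[s2] <- 1.0
  bg2 <- background_activity(pet2, m$ra, m$la)
  res2 <- ama(pet2, list(ascending = binary_mask(s1, c(1, 1, 1)),
                         arch = binary_mask(s2, c(1, 1, 1))), bg2)
  expect_equal(res2$sections$ama, c(1.2, 1.0))
  expect_equal(res2$overall, (1.2 * 40 + 1.0 * 20) / 60)
  # overall lies between the section values (volume-weighted mean)
  expect_gte(res2$overall, min(res2$sections$ama))
  expect_lte(res2$overall, max(res2$sections$ama))
})

test_that("AMA self-normalizes a VOI at blood-pool level to exactly 1", {
  m <- fixture_masks()
  pet <- fixture_grid(1)
  sec <- array(FALSE, c(10, 10, 8)); sec[4:6, 2:4, 5:7] <- TRUE
  bg <- background_activity(pet, m$ra, m$la)
  res <- ama(pet, list(ascending = binary_mask(sec, c(1, 1, 1))), bg)
  expect_identical(res$overall, 1)
})

test_that("the threshold removes voxels from numerator and denominator", {
  m <- fixture_masks()
  pet <- fixture_grid(1)
  sec <- array(FALSE, c(10, 10, 8)); sec[1:2, 5, 5:8] <- TRUE
  pet$values[1:2, 5, 5:8] <- c(1, 1, 2, 2, 2, 2, 3, 9)
  bg <- background_activity(pet, m$ra, m$la)
  res <- ama(pet, list(a = binary_mask(sec, c(1, 1, 1))), bg, threshold = 3)
  expect_equal(res$sections$volume_cm3, 7 * 0.001)
  expect_equal(res$overall, mean(c(1, 1, 2, 2, 2, 2, 3)))
  expect_equal(res$excluded, 1)
  expect_error(ama(pet, list(a = binary_mask(sec, c(1, 1, 1))), bg,
                   threshold = 0.5), "exceed")
})

test_that("AMA monotonicity: raising an included voxel cannot lower it", {
  m <- fixture_masks()
  sec <- array(FALSE, c(10, 10, 8)); sec[4:6, 2:4, 5:7] <- TRUE
  set.seed(3)
  pet <- fixture_grid(1)
  pet$values[sec] <- runif(sum(sec), 0.5, 2)
  bg <- background_activity(pet, m$ra, m$la)
  base <- ama(pet, list(a = binary_mask(sec, c(1, 1, 1))), bg)$overall
  pet$values[5, 3, 6] <- pet$values[5, 3, 6] + 0.7
  up <- ama(pet, list(a = binary_mask(sec, c(1, 1, 1))), bg)$overall
  expect_gte(up, base)
})

test_that("whole-vessel metrics average the per-slice series", {
  m <- fixture_masks()
  pet <- fixture_grid(1)
  disc <- matrix(FALSE, 10, 10); disc[4:6, 4:6] <- TRUE
  rois <- structure(list(slices = 5:7,
                         masks = list(disc, disc, disc),
                         slice_spacing = 1), class = "slice_roi_series")
  pet$values[4:6, 4:6, 5] <- 1
  pet$values[4:6, 4:6, 6] <- 1
  pet$values[4:6, 4:6, 7] <- 4
  bg <- background_activity(pet, m$ra, m$la)
  wv <- whole_vessel(pet, rois, bg)
  expect_equal(wv$per_slice$tbr_mean, c(1, 1, 4))
  expect_equal(wv$tbr_mean, 2)
  expect_equal(wv$tbr_max, 2)
  expect_true(all(wv$per_slice$suv_max >= wv$per_slice$suv_mean))

  pet$values[5, 5, 7] <- 6
  wv2 <- whole_vessel(pet, rois, bg)
  expect_equal(wv2$per_slice$suv_max, c(1, 1, 6))
  expect_gt(wv2$tbr_max, wv2$tbr_mean)
})

test_that("roi_stats returns the mean and max of one 2-D region", {
  pet <- fixture_grid(0)
  roi <- matrix(FALSE, 10, 10); roi[1:3, 1] <- TRUE
  pet$values[1:3, 1, 2] <- c(1, 2, 3)
  expect_equal(roi_stats(pet, roi, 2), c(suv_mean = 2, suv_max = 3))
  expect_error(roi_stats(pet, matrix(FALSE, 10, 10), 2), "empty")
})

mk_wv <- function(tbr_mean, tbr_max = tbr_mean, bg = 1) {
  structure(list(per_slice = data.frame(
    slice = seq_along(tbr_mean),
    suv_mean = tbr_mean * bg, suv_max = tbr_max * bg,
    tbr_mean = tbr_mean, tbr_max = tbr_max),
    tbr_mean = mean(tbr_mean), tbr_max = mean(tbr_max),
    suv_mean = mean(tbr_mean * bg), suv_max = mean(tbr_max * bg),
    n_slices = length(tbr_mean), background = bg),
    class = "whole_vessel_result")
}

test_that("most diseased segment finds the hottest 3-slice window", {
  mds <- most_diseased_segment(mk_wv(c(1, 1, 5, 5, 5, 1)))
  expect_equal(mds$tbr_mds_mean, 5)
  expect_equal(mds$window_mean_start, 3)

  mds2 <- most_diseased_segment(mk_wv(c(2, 2, 2, 2)))
  expect_equal(mds2$tbr_mds_mean, 2)
  expect_equal(mds2$window_mean_start, 1)  # proximal tie-break

  mds3 <- most_diseased_segment(mk_wv(c(3, 1, 1, 1, 1)))
  expect_equal(mds3$tbr_mds_mean, 5 / 3)
  expect_equal(mds3$window_mean_start, 1)

  expect_error(most_diseased_segment(mk_wv(c(1, 2))), "at least 3")
})

test_that("MDS windows for mean and max series are chosen independently", {
  wv <- mk_wv(tbr_mean = c(5, 5, 5, 1, 1, 1), tbr_max = c(1, 1, 1, 9, 9, 9))
  mds <- most_diseased_segment(wv)
  expect_equal(mds$window_mean_start, 1)
  expect_equal(mds$window_max_start, 4)
  expect_equal(mds$tbr_mds_mean, 5)
  expect_equal(mds$tbr_mds_max, 9)
})

test_that("time-delay correction applies the exponential clearance model", {
  m <- fixture_masks()
  bg <- background_activity(fixture_grid(1), m$ra, m$la)
  expect_equal(time_delay_correct(bg, 60, 60, 0.005)$value, bg$value)
  expect_equal(time_delay_correct(bg, 80, 60, 0)$value, bg$value)
  corrected <- time_delay_correct(bg, 80, 60, 0.005)
  expect_equal(corrected$value, bg$value * exp(0.1), tolerance = 1e-12)
  expect_false(is.null(corrected$correction))
  # the default pipeline applies no correction
  ph <- generate_phantom(clean_cfg())
  q <- quantify_aorta(ph$pet, truth_to_voi(ph$truth), threshold_ref = "off")
  expect_null(q$background$correction)
})
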