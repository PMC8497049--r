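test_that("section radius is half the lumen diameter plus 4 mm", {
  expect_equal(section_radius(30), 17)
  expect_equal(section_radius(26), 15)
  expect_equal(section_radius(0.001), 2.0005)
  expect_error(section_radius(0), "positive")
  expect_error(section_radius(-3), "positive")
})

test_that("tube_section validates its interval and derives its radius", {
  s <- tube_section("ascending", 0, 50, 30)
  expect_equal(s$voi_radius, 17)
  expect_error(tube_section("x", 10, 10, 30), "a < b")
  expect_error(tube_section("x", 20, 10, 30), "a < b")
})

test_that("a straight tube mask equals the brute-force cylinder test", {
  grid <- voxel_image(array(0, c(40, 40, 40)), spacing = c(1, 1, 1))
  cl <- centerline(cbind(20, 20, c(2, 38)))
  sec <- tube_section("ascending", 5, 30, 30)
  m <- build_tube_mask(grid, cl, sec)
  expect_identical(m$values, bf_tube_mask(grid, cl, sec))
  expect_gt(sum(m$values), 0)
})

test_that("adjacent sections are disjoint and their union is seamless", {
  grid <- voxel_image(array(0, c(40, 40, 48)), spacing = c(1.5, 1.5, 1.5))
  cl <- centerline(cbind(30, 30, c(3, 68)))
  a <- build_tube_mask(grid, cl, tube_section("ascending", 5, 30, 24))
  b <- build_tube_mask(grid, cl, tube_section("arch", 30, 55, 24))
  expect_false(any(a$values & b$values))
  joint <- build_tube_mask(grid, cl, tube_section("both", 5, 55, 24))
  expect_identical(a$values | b$values, joint$values)
})

test_that("tube masks grow monotonically with the VOI radius", {
  grid <- voxel_image(array(0, c(32, 32, 32)), spacing = c(2, 2, 2))
  cl <- centerline(cbind(c(30, 32, 34), c(30, 30, 32), c(10, 30, 50)))
  for (d in c(10, 16, 22)) {
    small <- build_tube_mask(grid, cl, tube_section("s", 5, 38, d))
    large <- build_tube_mask(grid, cl, tube_section("s", 5, 38, d + 6))
    expect_true(all(large$values[small$values]))
  }
})

test_that("mask construction is invariant under joint rigid translation", {
  base <- list(values = array(0, c(24, 24, 24)), spacing = c(2, 2, 2))
  shift <- c(13.7, -4.2, 8.9)
  pts <- cbind(c(24, 25, 26), c(24, 24, 23), c(6, 24, 42))
  sec <- tube_section("s", 2, 35, 14)
  g0 <- voxel_image(base$values, base$spacing, c(0, 0, 0))
  g1 <- voxel_image(base$values, base$spacing, shift)
  m0 <- build_tube_mask(g0, centerline(pts), sec)
  m1 <- build_tube_mask(g1, centerline(sweep(pts, 2, -shift)), sec)
  expect_identical(m0$values, m1$values)
  s0 <- sphere_mask(g0, c(24, 24, 24))
  s1 <- sphere_mask(g1, c(24, 24, 24) + shift)
  expect_identical(s0$values, s1$values)
})

test_that("the 2-cm^3 sphere voxelizes to its analytic volume", {
  grid <- voxel_image(array(0, c(30, 30, 30)), spacing = c(1, 1, 1))
  m <- sphere_mask(grid, c(14.5, 14.5, 14.5), volume = 2)
  expect_identical(m$values, bf_sphere_mask(grid, c(14.5, 14.5, 14.5), 2))
  vol <- mask_volume(m)
  expect_gte(vol, 1.9)
  expect_lte(vol, 2.1)
  # determinism
  expect_identical(m$values, sphere_mask(grid, c(14.5, 14.5, 14.5))$values)
})

test_that("sphere masks handle degenerate volumes and bad centers", {
  grid <- voxel_image(array(0, c(20, 20, 20)), spacing = c(2, 2, 2))
  tiny <- sphere_mask(grid, c(20, 20, 20), volume = 1e-9)
  expect_lte(sum(tiny$values), 1)
  expect_error(sphere_mask(grid, c(200, 20, 20)), "outside")
})

test_that("slice ROIs of a vertical cylinder are identical discs", {
  grid <- voxel_image(array(0, c(40, 40, 36)), spacing = c(1, 1, 1))
  cl <- centerline(cbind(20, 20, c(0, 35)))
  secs <- list(tube_section("s", 0, 35, 20))
  rois <- slice_rois(grid, cl, secs, c(3, 32))
  expect_length(rois$slices, 30)
  ref <- rois$masks[[1]]
  for (m in rois$masks) expect_identical(m, ref)
  # oracle: each 2-D mask is the 3-D tube mask sliced at that z
  tube <- build_tube_mask(grid, cl, secs[[1]])
  for (q in seq_along(rois$slices))
    expect_identical(rois$masks[[q]], tube$values[, , rois$slices[q]])
})

test_that("empty edge slices are dropped with a warning, empty series errors", {
  grid <- voxel_image(array(0, c(30, 30, 40)), spacing = c(1, 1, 1))
  cl <- centerline(cbind(15, 15, c(10, 25)))
  secs <- list(tube_section("s", 0, 15, 10))
  expect_warning(rois <- slice_rois(grid, cl, secs, c(1, 40)), "dropped")
  expect_true(all(vapply(rois$masks, any, logical(1))))
  expect_error(slice_rois(grid, cl, secs, c(35, 40)), "no slice")
  expect_error(slice_rois(grid, cl, secs, c(1, 99)), "z-extent")
})
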