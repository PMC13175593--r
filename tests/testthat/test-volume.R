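test_that("ct_volume validates its invariants", {
  expect_error(ct_volume(array(0, c(4, 4)), c(1, 1, 1)), "3-D")
  expect_error(ct_volume(array(0, c(4, 4, 1)), c(1, 1, 1)), ">= 2")
  expect_error(ct_volume(array(0, c(4, 4, 4)), c(1, 0, 1)), "positive")
  v <- ct_volume(array(100, c(4, 5, 6)), c(0.5, 0.5, 1), c(-1, -2, -3))
  expect_identical(dim(v$voxels), c(4L, 5L, 6L))
})

test_that("NIfTI write/read round-trips voxels, spacing and origin", {
  ph <- make_phantom_fixture(shape = c(24, 24, 16), spacing = c(0.5, 0.5, 1),
                             semi = c(5, 5, 6), thickness = 2)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, f)
  v2 <- load_volume(f, "nifti")
  expect_equal(v2$spacing, c(0.5, 0.5, 1), tolerance = 1e-6)
  expect_equal(v2$origin, ph$volume$origin, tolerance = 1e-4)
  expect_equal(as.vector(v2$voxels), as.vector(ph$volume$voxels),
               tolerance = 1e-4)
  expect_error(load_volume(tempfile(fileext = ".nii")), "does not exist")
})

test_that("degenerate NIfTI axes are rejected", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(8, 8, 1)))
  RNifti::writeNifti(img, f)
  expect_error(load_volume(f), "degenerate axis|3-D volume")
})

test_that("smoothing with sigma 0 is pure thresholding", {
  set.seed(3)
  v <- ct_volume(array(rnorm(20^3, 300, 400), c(20, 20, 20)), c(1, 1, 1))
  m <- smooth_and_threshold(v, sigma_mm = 0, hu_threshold = 300)
  expect_identical(m$voxels, array(v$voxels >= 300, dim(v$voxels)))
  u <- ct_volume(array(1000, c(4, 4, 4)), c(1, 1, 1))
  expect_true(all(smooth_and_threshold(u, 0, 300)$voxels))
  z <- ct_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  expect_false(any(smooth_and_threshold(z, 0, 300)$voxels))
})

test_that("threshold mask of a phantom shell matches the analytic voxel count", {
  ph <- make_phantom_fixture(noise_sd = 0)
  m <- smooth_and_threshold(ph$volume, sigma_mm = 0.5, hu_threshold = 300)
  a <- ph$spec$semi_axes; t <- ph$spec$thickness
  analytic <- 4 / 3 * pi * (prod(a) - prod(a - t)) / prod(ph$spec$spacing)
  expect_lt(abs(sum(m$voxels) - analytic) / analytic, 0.05)
  # and the generator's own voxelized truth is even closer
  expect_lt(abs(sum(m$voxels) - ph$shell_voxel_count) /
              ph$shell_voxel_count, 0.02)
})

test_that("largest_component keeps the biggest blob and is idempotent", {
  vox <- array(FALSE, c(30, 30, 10))
  vox[2:11, 2:11, 2:4] <- TRUE            # 300 voxels
  vox[20:22, 20:22, 6:8] <- TRUE          # 27-voxel 'head holder'
  m <- binary_mask(vox, c(1, 1, 1))
  r <- largest_component(m)
  expect_equal(sum(r$voxels), 300)
  expect_false(any(r$voxels[20:22, 20:22, 6:8]))
  expect_identical(largest_component(r)$voxels, r$voxels)
  expect_error(largest_component(binary_mask(array(FALSE, c(3, 3, 3)),
                                             c(1, 1, 1))),
               "empty segmentation")
  expect_error(largest_component(m, connectivity = 4), "connectivity")
})

test_that("equal-size components tie-break on the lowest linear index", {
  vox <- array(FALSE, c(12, 6, 6))
  vox[9:10, 2:3, 2:3] <- TRUE   # 8 voxels, higher linear indices
  vox[2:3, 2:3, 2:3] <- TRUE    # 8 voxels, contains the lowest index
  r <- largest_component(binary_mask(vox, c(1, 1, 1)))
  expect_true(all(r$voxels[2:3, 2:3, 2:3]))
  expect_false(any(r$voxels[9:10, , ]))
})

test_that("per-slice closing fills rings and bridges small gaps", {
  # closed ring slice -> interior filled
  vox <- array(FALSE, c(24, 24, 3))
  th <- seq(0, 2 * pi, length.out = 200)
  xs <- round(12 + 8 * cos(th)); ys <- round(12 + 8 * sin(th))
  vox[cbind(xs, ys, 2)] <- TRUE
  filled <- axial_close_and_fill(binary_mask(vox, c(1, 1, 1)), 0, 0)
  expect_true(filled$voxels[12, 12, 2])
  # a slice the ring is absent from stays empty
  expect_false(any(filled$voxels[, , 1]))

  # ring with a 1-voxel gap: dilate_r = 1 closes it; verify with the
  # flood-fill oracle that no interior pixel remains reachable from outside
  gap <- vox
  gap[cbind(xs, ys, 2)] <- TRUE
  gap[20, 12, 2] <- FALSE
  closed <- axial_close_and_fill(binary_mask(gap, c(1, 1, 1)), 1, 1)
  reach <- flood_from_border(closed$voxels[, , 2])
  expect_true(closed$voxels[12, 12, 2])
  expect_false(reach[12, 12])
  # outer contour restored to about the original radius after erosion
  expect_false(any(closed$voxels[1:2, , 2]))
  expect_error(axial_close_and_fill(filled, 1, 2), "dilate_r >= erode_r")
})

test_that("surface points are the exposed voxel shell in world mm", {
  vox <- array(FALSE, c(5, 5, 5))
  vox[2:4, 2:4, 2:4] <- TRUE
  sp <- extract_surface_points(binary_mask(vox, c(0.5, 0.5, 2), c(10, 0, -5)))
  expect_equal(nrow(sp$points), 26)       # all but the centre voxel
  expect_false(any(apply(sp$points, 1, function(p)
    all(p == c(10 + 2 * 0.5, 2 * 0.5, -5 + 2 * 2)))))
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(nrow(extract_surface_points(
    binary_mask(one, c(1, 1, 1)))$points), 1)
  expect_equal(extract_surface_points(
    binary_mask(one, c(1, 1, 1)))$points[1, ], c(x = 1, y = 1, z = 1))
  expect_error(extract_surface_points(binary_mask(array(FALSE, c(3, 3, 3)),
                                                  c(1, 1, 1))), "empty")
})

test_that("ball surface count matches brute-force scan and sphere area", {
  r <- 10
  g <- as.matrix(expand.grid(x = 1:23, y = 1:23, z = 1:23))
  vox <- array(FALSE, c(23, 23, 23))
  vox[g[rowSums((g - 12)^2) <= r^2, ]] <- TRUE
  sp <- extract_surface_points(binary_mask(vox, c(1, 1, 1)))
  oracle <- brute_boundary_voxels(vox)
  expect_equal(nrow(sp$points), nrow(oracle))
  expect_setequal(paste(sp$points[, 1], sp$points[, 2], sp$points[, 3]),
                  paste(oracle[, 1] - 1, oracle[, 2] - 1, oracle[, 3] - 1))
  # analytic voxel-shell estimate: unit-thickness spherical shell volume;
  # staircase discretization scatters the true count around it
  shell <- 4 / 3 * pi * (r^3 - (r - 1)^3)
  expect_lt(abs(nrow(sp$points) - shell) / shell, 0.25)
})

test_that("surface points sit on the mask boundary (removal property)", {
  ph <- make_phantom_fixture(shape = c(40, 40, 40), spacing = rep(1, 3),
                             semi = c(15, 13, 16), thickness = 4)
  solid <- axial_close_and_fill(
    largest_component(smooth_and_threshold(ph$volume, 0, 300)), 2, 2)
  sp <- extract_surface_points(solid)
  idx <- sweep(sweep(sp$points, 2, solid$origin), 2, solid$spacing, "/") + 1
  idx <- matrix(as.integer(round(idx)), ncol = 3)
  expect_true(all(solid$voxels[idx]))     # subset of true voxels
  # removing the shell leaves no true voxel exposed
  inner <- solid$voxels
  inner[idx] <- FALSE
  if (any(inner)) {
    ob <- brute_boundary_voxels(inner)
    d <- dim(inner)
    edge <- ob[, 1] %in% c(1, d[1]) | ob[, 2] %in% c(1, d[2]) |
      ob[, 3] %in% c(1, d[3])
    # every remaining boundary voxel of the eroded mask was exposed only
    # through the removed shell, not through background
    for (ri in which(!edge)) {
      p <- ob[ri, ]
      nb <- rbind(p + c(1, 0, 0), p - c(1, 0, 0), p + c(0, 1, 0),
                  p - c(0, 1, 0), p + c(0, 0, 1), p - c(0, 0, 1))
      vals_solid <- solid$voxels[nb]
      vals_inner <- inner[nb]
      expect_true(all(vals_solid[!vals_inner]))
    }
  }
})
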