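test_that("volume NIfTI round trip preserves voxels and geometry", {
  set.seed(1)
  v <- image_volume(array(rnorm(10 * 10 * 10), c(10, 10, 10)),
                    spacing = c(1.37, 1.37, 3.0), origin = c(-5, 8, 2.5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$geometry$spacing, c(1.37, 1.37, 3.0))
  expect_equal(v2$geometry$origin, c(-5, 8, 2.5))
  expect_equal(v2$geometry$orientation, diag(3))
})

test_that("reading a 2-D image or degenerate geometry fails loudly", {
  f <- tempfile(fileext = ".nii.gz")
  im <- RNifti::asNifti(matrix(1:20, 4, 5))
  RNifti::writeNifti(im, f)
  expect_error(read_volume(f), "3-D")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  expect_error(grid_geometry(c(4, 4, 4), spacing = c(1, 0, 1)),
               "degenerate spacing")
  expect_error(image_volume(array(0, c(3, 3))), "3-D")
})

test_that("physical coordinate mapping is affine and invertible", {
  th <- 0.4
  R <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  g <- grid_geometry(c(12, 10, 8), c(1.37, 1.37, 3), c(10, -4, 2), R)
  set.seed(2)
  idx <- cbind(runif(50, 0, 11), runif(50, 0, 9), runif(50, 0, 7))
  w <- voxel_to_world(g, idx)
  expect_lt(max(abs(world_to_voxel(g, w) - idx)), 1e-9)
  # voxel (0,0,0) sits at the origin
  expect_equal(as.numeric(voxel_to_world(g, cbind(0, 0, 0))), c(10, -4, 2))
})

test_that("landmark CSV and JSON round trip; malformed input is rejected", {
  lms <- landmark_set(data.frame(name = c("L1", "L2", "L3"),
                                 x = c(0, 1.25, -3.5), y = c(0, -2, 7.125),
                                 z = c(0, 3, 0.001)), frame = "fixed")
  for (ext in c(".csv", ".json")) {
    f <- tempfile(fileext = ext)
    write_landmarks(lms, f)
    l2 <- read_landmarks(f, frame = "fixed")
    expect_equal(as.matrix(l2$points[, 2:4]), as.matrix(lms$points[, 2:4]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(l2$points$name, lms$points$name)
  }
  f <- tempfile(fileext = ".csv")
  writeLines(c("name,x,y,z", "L1,0,0,0", "L1,1,1,1"), f)
  expect_error(read_landmarks(f), "duplicate")
  writeLines(c("name,x,y,z", "L1,0,zero,0"), f)
  expect_error(read_landmarks(f), "non-numeric")
  # single point parses to the origin
  writeLines(c("name,x,y,z", "L1,0,0,0"), f)
  l1 <- read_landmarks(f)
  expect_equal(nrow(l1$points), 1L)
  expect_equal(as.numeric(l1$points[1, 2:4]), c(0, 0, 0))
})

test_that("pairing landmark sets requires equal name sets", {
  a <- landmark_set(data.frame(name = c("A", "B"), x = 0, y = 0, z = 0))
  b <- landmark_set(data.frame(name = c("A", "C"), x = 1, y = 1, z = 1))
  expect_error(pair_landmarks(a, b), "not paired")
})

test_that("displacement field round trip is exact; bad component count fails", {
  g <- grid_geometry(c(6, 5, 4), c(2, 2, 2.5))
  zero <- displacement_field(array(0, c(6, 5, 4, 3)), g)
  f <- tempfile(fileext = ".nii.gz")
  write_dvf(zero, f)
  expect_equal(read_dvf(f)$vectors, zero$vectors)
  cst <- zero
  for (a in 1:3) cst$vectors[, , , a] <- a
  write_dvf(cst, f)
  back <- read_dvf(f)
  expect_identical(back$vectors, cst$vectors)
  expect_true(file.exists(sub("\\.nii\\.gz$", ".yaml", f)))
  # four components is not a displacement field
  bad <- RNifti::asNifti(array(0, c(6, 5, 4, 4)))
  f4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(bad, f4)
  expect_error(read_dvf(f4), "3 components")
})

test_that("resampling a field preserves constants and affine ramps", {
  g <- grid_geometry(c(10, 10, 10), c(2, 2, 2))
  cst <- displacement_field(
    array(rep(c(1, 2, 3), each = 1000), c(10, 10, 10, 3)), g)
  fine <- grid_geometry(c(12, 12, 12), c(1, 1, 1), origin = c(2, 2, 2))
  out <- resample_to_grid(cst, fine)
  expect_lt(max(abs(out$vectors[, , , 1] - 1)), 1e-12)
  expect_lt(max(abs(out$vectors[, , , 3] - 3)), 1e-12)
  # linear ramp u_x = 0.1 x reproduced exactly at a finer grid
  ramp <- to_displacement_field(function(p) cbind(p[, 1] * 1.1, p[, 2], p[, 3]), g)
  out2 <- resample_to_grid(ramp, fine)
  xs <- voxel_to_world(fine, cbind(0:11, 0, 0))[, 1]
  expect_lt(max(abs(out2$vectors[, 1, 1, 1] - 0.1 * xs)), 1e-9)
  # resampling onto the field's own grid is the identity
  out3 <- resample_to_grid(ramp, g)
  expect_equal(out3$vectors, ramp$vectors, tolerance = 1e-12)
  # disjoint grids are an error
  far <- grid_geometry(c(4, 4, 4), c(1, 1, 1), origin = c(500, 500, 500))
  expect_error(resample_to_grid(cst, far), "disjoint")
})

test_that("mask volume is voxel count times voxel volume", {
  labs <- array(0L, c(4, 4, 4))
  labs[1:2, 1:2, 1:2] <- 1L
  m1 <- structure_mask(labs, grid_geometry(c(4, 4, 4), c(1, 1, 1)),
                       c(cube = 1L, empty = 2L))
  expect_equal(mask_volume_mm3(m1, "cube"), 8)
  m2 <- structure_mask(labs, grid_geometry(c(4, 4, 4), c(1.37, 1.37, 3)),
                       c(cube = 1L, empty = 2L))
  expect_equal(mask_volume_mm3(m2, "cube"), 8 * 1.37 * 1.37 * 3,
               tolerance = 1e-12)
  expect_equal(mask_volume_mm3(m2, "empty"), 0)
  expect_error(mask_volume_mm3(m2, 9), "unknown label")
  expect_error(mask_volume_mm3(m2, "nope"), "unknown label")
})
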