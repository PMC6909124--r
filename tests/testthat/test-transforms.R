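naive_bspline_disp <- function(tr, x) {
  # independent tensor-product cubic B-spline summation
  B3 <- function(i, u) switch(i + 1,
                              (1 - u)^3 / 6,
                              (3 * u^3 - 6 * u^2 + 4) / 6,
                              (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
                              u^3 / 6)
  t <- (x - tr$lattice_origin) / tr$control_spacing
  i <- floor(t); u <- t - i
  acc <- c(0, 0, 0)
  for (kx in 0:3) for (ky in 0:3) for (kz in 0:3) {
    w <- B3(kx, u[1]) * B3(ky, u[2]) * B3(kz, u[3])
    acc <- acc + w * tr$coef[i[1] + kx, i[2] + ky, i[3] + kz, ]
  }
  acc
}

test_that("rigid transforms preserve distances and invert exactly", {
  set.seed(3)
  for (rep in 1:5) {
    tr <- rigid_transform(rnorm(3, sd = 5), rnorm(3, sd = 0.3),
                          center = rnorm(3, sd = 10))
    p <- matrix(rnorm(60, sd = 30), 20, 3)
    q <- apply_to_points(tr, p)
    expect_lt(max(abs(dist(q) - dist(p))), 1e-9)
    back <- apply_to_points(invert_rigid(tr), q)
    expect_lt(max(abs(back - p)), 1e-9)
  }
})

test_that("translations and rigid composition behave in closed form", {
  t1 <- rigid_transform(c(1, 0, 0))
  t2 <- rigid_transform(c(0, 1, 0))
  comp <- compose_transforms(t1, t2)
  expect_s3_class(comp, "rigid_transform")
  expect_equal(comp$translation, c(1, 1, 0))
  p <- matrix(c(3, 4, 0), 1)
  expect_equal(as.numeric(apply_to_points(rigid_transform(c(3, 4, 0)), p)),
               c(6, 8, 0))
  # identity leaves landmark sets untouched
  lms <- landmark_set(data.frame(name = c("a", "b"), x = c(1, 2),
                                 y = c(3, 4), z = c(5, 6)))
  out <- apply_to_points(rigid_transform(), lms)
  expect_equal(out$points, lms$points)
})

test_that("B-spline displacement matches naive De Boor summation", {
  set.seed(4)
  tr <- bspline_transform(rbind(c(-40, -40, -40), c(40, 40, 40)),
                          c(17, 23, 30))
  tr$coef[] <- rnorm(length(tr$coef), sd = 3)
  pts <- cbind(runif(25, -35, 35), runif(25, -35, 35), runif(25, -35, 35))
  got <- apply_to_points(tr, pts) - pts
  want <- t(apply(pts, 1, function(x) naive_bspline_disp(tr, x)))
  expect_lt(max(abs(got - want)), 1e-9)
  # zero coefficients give the identity
  tr0 <- bspline_transform(rbind(c(-40, -40, -40), c(40, 40, 40)), c(20, 20, 20))
  expect_equal(apply_to_points(tr0, pts), pts)
  # points outside the domain are rejected
  expect_error(apply_to_points(tr, rbind(c(500, 0, 0))), "outside")
})

test_that("changing one coefficient only alters the field inside its support", {
  tr <- bspline_transform(rbind(c(0, 0, 0), c(100, 100, 100)), c(20, 20, 20))
  tr2 <- tr
  ci <- c(4, 4, 4)   # a central control point
  tr2$coef[ci[1], ci[2], ci[3], 1] <- 5
  g <- grid_geometry(c(21, 21, 21), c(5, 5, 5))
  d1 <- to_displacement_field(tr, g)
  d2 <- to_displacement_field(tr2, g)
  diffmag <- sqrt(apply((d2$vectors - d1$vectors)^2, 1:3, sum))
  pts <- grid_points(g)
  # support of control point i spans (i-2, i+2) knot spacings
  cp_pos <- tr$lattice_origin + (ci - 1) * tr$control_spacing
  inside <- apply(abs(sweep(pts, 2, cp_pos, "-")), 1,
                  function(r) all(r < 2 * 20))
  expect_true(all(diffmag[!array(inside, g$dim)] < 1e-12))
  expect_true(any(diffmag[array(inside, g$dim)] > 1e-3))
})

test_that("volume resampling matches array shifts for integer translations", {
  set.seed(5)
  arr <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  vol <- image_volume(arr, spacing = c(2, 2, 2))
  # translation by exactly one voxel along x, nearest neighbour:
  # output(x) = moving(x + 2mm) so the array shifts down by one index
  tr <- rigid_transform(c(2, 0, 0))
  out <- apply_to_volume(tr, vol, vol$geometry, "nearest")
  expect_equal(out$voxels[1:7, , ], arr[2:8, , ])
  # identity on the same grid is exact
  out2 <- apply_to_volume(rigid_transform(), vol, vol$geometry, "linear")
  expect_lt(max(abs(out2$voxels - arr)), 1e-9)
  # nearest interpolation keeps masks integer-valued
  labs <- array(sample(0:2, 8^3, replace = TRUE), c(8, 8, 8))
  msk <- structure_mask(labs, vol$geometry, c(a = 1L, b = 2L))
  wm <- apply_to_mask(rigid_transform(c(1.1, -0.7, 0.4)), msk, vol$geometry)
  expect_true(all(wm$labels == round(wm$labels)))
  expect_true(all(wm$labels %in% 0:2))
})

test_that("transform sampling onto a grid agrees with point application", {
  set.seed(6)
  tr <- bspline_transform(rbind(c(-60, -60, -60), c(60, 60, 60)), c(25, 25, 25))
  tr$coef[] <- rnorm(length(tr$coef), sd = 2)
  g <- grid_geometry(c(9, 9, 9), c(5, 5, 5), origin = c(-20, -20, -20))
  fld <- to_displacement_field(tr, g)
  pts <- grid_points(g)
  direct <- apply_to_points(tr, pts)
  expect_lt(max(abs((pts + matrix(fld$vectors, ncol = 3)) - direct)), 1e-9)
  # identity and translation closed forms
  expect_true(all(to_displacement_field(rigid_transform(), g)$vectors == 0))
  tf <- to_displacement_field(rigid_transform(c(1, 2, 3)), g)
  expect_equal(range(tf$vectors[, , , 1]), c(1, 1))
  expect_equal(range(tf$vectors[, , , 3]), c(3, 3))
})

test_that("general composition equals pointwise evaluation on random points", {
  set.seed(7)
  bs <- bspline_transform(rbind(c(-80, -80, -80), c(80, 80, 80)), c(30, 30, 30))
  bs$coef[] <- rnorm(length(bs$coef), sd = 2)
  rg <- rigid_transform(c(4, -2, 1), c(0.05, -0.02, 0.04), center = c(0, 0, 0))
  comp <- compose_transforms(bs, rg)
  pts <- matrix(runif(300, -40, 40), 100, 3)
  want <- apply_to_points(bs, apply_to_points(rg, pts))
  expect_lt(max(abs(apply_to_points(comp, pts) - want)), 1e-12)
  # T o T^-1 is the identity
  ti <- compose_transforms(rg, invert_rigid(rg))
  expect_lt(max(abs(apply_to_points(ti, pts) - pts)), 1e-9)
})
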