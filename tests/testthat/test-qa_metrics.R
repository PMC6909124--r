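cube_mask <- function(lo, hi, dim = c(8, 8, 8), spacing = c(1, 1, 1)) {
  labs <- array(0L, dim)
  labs[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  structure_mask(labs, grid_geometry(dim, spacing), c(structure = 1L))
}

sphere_mask <- function(radius, dim = c(51, 51, 51), spacing = c(1, 1, 1)) {
  g <- grid_geometry(dim, spacing, origin = -(dim - 1) * spacing / 2)
  r <- sqrt(rowSums(grid_points(g)^2))
  structure_mask(array(as.integer(r <= radius), dim), g, c(sphere = 1L))
}

test_that("DSC closed forms: identity, disjoint, shifted cube, symmetry", {
  a <- cube_mask(c(2, 2, 2), c(3, 3, 3))
  expect_equal(dice(a, a), 1.0)
  b <- cube_mask(c(3, 2, 2), c(4, 3, 3))     # shift by 1 voxel along x
  expect_equal(dice(a, b), 2 * 4 / (8 + 8))
  d <- cube_mask(c(6, 6, 6), c(7, 7, 7))
  expect_equal(dice(a, d), 0.0)
  # symmetry, exactly
  set.seed(8)
  for (i in 1:5) {
    m1 <- random_mask(); m2 <- random_mask()
    expect_identical(dice(m1, m2), dice(m2, m1))
  }
  empty <- cube_mask(c(1, 1, 1), c(1, 1, 1))
  empty$labels[] <- 0L
  expect_error(dice(empty, empty), "empty")
})

test_that("MDA equals the exhaustive all-pairs oracle on random masks", {
  set.seed(9)
  for (i in 1:12) {
    a <- random_mask(dim = c(7, 8, 6), spacing = runif(3, 0.8, 3))
    b <- random_mask(dim = c(7, 8, 6), spacing = a$geometry$spacing)
    expect_equal(mean_distance_to_agreement(b, a), oracle_mda(b, a),
                 tolerance = 1e-12)
    # symmetric variant is the mean of the two directed values
    expect_equal(mean_distance_to_agreement(b, a, symmetric = TRUE),
                 (oracle_mda(b, a) + oracle_mda(a, b)) / 2,
                 tolerance = 1e-12)
  }
  a <- cube_mask(c(2, 2, 2), c(4, 4, 4))
  expect_equal(mean_distance_to_agreement(a, a), 0)
})

test_that("MDA of concentric spheres approximates the radial gap", {
  inner <- sphere_mask(20)
  outer <- sphere_mask(24)
  expect_lt(abs(mean_distance_to_agreement(outer, inner) - 4), 0.7)
})

test_that("TRE is the per-landmark Euclidean distance with summaries", {
  a <- landmark_set(data.frame(name = c("p", "q"), x = c(0, 10), y = c(0, 0),
                               z = c(0, 5)))
  expect_equal(target_registration_error(a, a)$pairs$tre_mm, c(0, 0))
  b <- a; b$points$x <- b$points$x + 3; b$points$y <- b$points$y + 4
  tre <- target_registration_error(b, a)
  expect_equal(tre$pairs$tre_mm, c(5, 5))
  # 124 random pairs against a direct element-wise recomputation
  set.seed(10)
  nm <- paste0("L", 1:124)
  p1 <- landmark_set(data.frame(name = nm, x = rnorm(124), y = rnorm(124),
                                z = rnorm(124)))
  p2 <- landmark_set(data.frame(name = sample(nm), x = rnorm(124),
                                y = rnorm(124), z = rnorm(124)))
  tre <- target_registration_error(p1, p2)
  m1 <- as.matrix(p1$points[, 2:4])
  ord <- match(p1$points$name, p2$points$name)
  m2 <- as.matrix(p2$points[ord, 2:4])
  want <- sqrt(rowSums((m1 - m2)^2))
  expect_equal(tre$pairs$tre_mm, want, tolerance = 1e-12)
  expect_equal(tre$median, median(want))
  expect_equal(tre$mean, mean(want))
  expect_equal(tre$sem, sd(want) / sqrt(124))
  expect_equal(tre$range, range(want))
})

test_that("Jacobian map closed forms hold", {
  g <- grid_geometry(c(12, 11, 10), c(1.37, 1.37, 3))
  zero <- displacement_field(array(0, c(12, 11, 10, 3)), g)
  jm <- jacobian_map(zero)
  expect_true(all(abs(jm$values[jm$validity] - 1) < 1e-12))
  # uniform linear contraction u = c x gives J = (1+c)^3; c chosen to give
  # a ~20 percent volume loss
  cval <- -0.0717
  lin <- to_displacement_field(function(p) p * (1 + cval), g)
  jl <- jacobian_map(lin)
  expect_lt(max(abs(jl$values[jl$validity] - (1 + cval)^3)), 1e-6)
  # a slab fold u_x = -2x has J = -1 inside the slab
  fold <- function(p) {
    u <- matrix(0, nrow(p), 3)
    inside <- abs(p[, 1] - 8) < 3
    u[inside, 1] <- -2 * (p[, 1][inside] - 8)
    p + u
  }
  jf <- jacobian_map(to_displacement_field(fold, g))
  xs <- voxel_to_world(g, cbind(0:11, 0, 0))[, 1]
  deep <- which(abs(xs - 8) < 3 - 2 * 1.37)   # interior of the slab
  edge <- which(abs(xs - 8) > 3 + 2 * 1.37)
  expect_true(all(jf$values[deep, 2:10, 2:9] < 0))
  expect_true(all(jf$values[edge, 2:10, 2:9] > 0))
  expect_error(jacobian_map(displacement_field(array(0, c(2, 5, 5, 3)),
                                               grid_geometry(c(2, 5, 5)))),
               "at least 3")
})

test_that("negative Jacobian fraction counts folded voxels in the mask", {
  g <- grid_geometry(c(20, 12, 12), c(1, 1, 1))
  mask <- structure_mask(array(1L, g$dim), g, c(all = 1L))
  zero <- displacement_field(array(0, c(g$dim, 3)), g)
  expect_equal(negative_jacobian_fraction(jacobian_map(zero), mask), 0)
  # fold occupying x in (3.5, 8.5): 5 of the 18 interior x-slabs; with
  # central differences the detected region may shrink by one boundary
  # voxel layer on each side, so the expected percentage brackets 5/18
  # from below down to 3/18
  fold <- function(p) {
    u <- matrix(0, nrow(p), 3)
    inside <- abs(p[, 1] - 6) < 2.5
    u[inside, 1] <- -2 * (p[, 1][inside] - 6)
    p + u
  }
  jf <- jacobian_map(to_displacement_field(fold, g))
  pct <- negative_jacobian_fraction(jf, mask)
  expect_gte(pct, 100 * 3 / 18 - 1e-9)
  expect_lte(pct, 100 * 5 / 18 + 1e-9)
  whole <- to_displacement_field(function(p) -2 * p, g)
  expect_equal(negative_jacobian_fraction(jacobian_map(whole), mask), 100)
})

test_that("cumulative displacement histogram counts masked magnitudes", {
  g <- grid_geometry(c(10, 10, 10), c(1, 1, 1))
  mask <- structure_mask(array(1L, g$dim), g, c(all = 1L))
  cst <- displacement_field(array(rep(c(3, 0, 4), each = 1000),
                                  c(10, 10, 10, 3)), g)   # |u| = 5
  h <- cumulative_displacement_histogram(cst, mask, bin_width_mm = 1)
  expect_equal(h$curve$cumulative_fraction[h$curve$threshold_mm < 5],
               rep(0, sum(h$curve$threshold_mm < 5)))
  expect_equal(h$curve$cumulative_fraction[h$curve$threshold_mm >= 5],
               rep(1, sum(h$curve$threshold_mm >= 5)))
  zero <- displacement_field(array(0, c(10, 10, 10, 3)), g)
  hz <- cumulative_displacement_histogram(zero, mask)
  expect_equal(hz$curve$cumulative_fraction[1], 1)
  # two-level field: half the voxels at 2 mm, half at 8 mm
  vec <- array(0, c(10, 10, 10, 3))
  vec[1:5, , , 1] <- 2
  vec[6:10, , , 1] <- 8
  hm <- cumulative_displacement_histogram(displacement_field(vec, g), mask,
                                          bin_width_mm = 1)
  cf <- function(t) hm$curve$cumulative_fraction[hm$curve$threshold_mm == t]
  expect_equal(cf(4), 0.5)
  expect_equal(cf(8), 1.0)
  expect_equal(hm$mean, 5)
  # contract: monotone and ends at 1
  expect_true(all(diff(hm$curve$cumulative_fraction) >= 0))
  expect_equal(tail(hm$curve$cumulative_fraction, 1), 1)
})

test_that("growing a structure toward its target raises DSC and lowers MDA", {
  target <- sphere_mask(20, dim = c(45, 45, 45))
  dscs <- c(); mdas <- c()
  for (r in c(8, 12, 16, 20)) {
    b <- sphere_mask(r, dim = c(45, 45, 45))
    dscs <- c(dscs, dice(target, b))
    mdas <- c(mdas, mean_distance_to_agreement(b, target))
  }
  expect_true(all(diff(dscs) > 0))
  expect_true(all(diff(mdas) < 0))
})
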