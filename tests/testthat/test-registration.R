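test_that("NMI reporting form: self-similarity, symmetry, oracle", {
  set.seed(17)
  a <- image_volume(array(rnorm(16^3), c(16, 16, 16)))
  expect_equal(nmi(a, a), 2, tolerance = 1e-9)
  b <- image_volume(array(rnorm(16^3), c(16, 16, 16)))
  expect_identical(nmi(a, b), nmi(b, a))
  # independent uniform images: NMI near 1 plus the finite-sample bias
  # computed by an explicit joint-histogram oracle on the same arrays
  u1 <- image_volume(array(runif(32^3), c(32, 32, 32)))
  u2 <- image_volume(array(runif(32^3), c(32, 32, 32)))
  got <- nmi(u1, u2, bins = 64)
  fb <- pmin(floor(u1$voxels / max(u1$voxels + 1e-12) * 64), 63)
  mb <- pmin(floor(u2$voxels / max(u2$voxels + 1e-12) * 64), 63)
  joint <- table(fb, mb)
  p <- joint / sum(joint)
  hj <- -sum(p[p > 0] * log(p[p > 0]))
  pf <- rowSums(p); pm <- colSums(p)
  oracle <- (-sum(pf[pf > 0] * log(pf[pf > 0])) -
               sum(pm[pm > 0] * log(pm[pm > 0]))) / hj
  expect_lt(abs(got - oracle), 0.05)
  expect_gt(got, 1)
  cst <- image_volume(array(1, c(16, 16, 16)))
  expect_error(nmi(cst, a), "constant")
})

test_that("correspondence construction pairs surfaces and landmarks", {
  dim <- c(45, 45, 45)
  g <- grid_geometry(dim, c(1, 1, 1), origin = -(dim - 1) / 2)
  r <- sqrt(rowSums(grid_points(g)^2))
  s20 <- structure_mask(array(as.integer(r <= 20), dim), g, c(s = 1L))
  s22 <- structure_mask(array(as.integer(r <= 22), dim), g, c(s = 1L))
  # identical masks: every pair distance is zero
  cs <- build_correspondences(s20, s20, n_surface_points = 200, seed = 2)
  expect_equal(max(sqrt(rowSums((cs$p_fixed - cs$p_moving)^2))), 0)
  # concentric spheres of radii 20 and 22: mean pair distance about 2 mm
  cs2 <- build_correspondences(s20, s22, n_surface_points = 300, seed = 2)
  expect_lt(abs(mean(sqrt(rowSums((cs2$p_fixed - cs2$p_moving)^2))) - 2),
            0.6)
  # landmark-only guidance keeps exactly the name-matched pairs
  lf <- landmark_set(data.frame(name = paste0("L", 1:6), x = rnorm(6),
                                y = rnorm(6), z = rnorm(6)))
  lm <- apply_to_points(rigid_transform(c(1, 1, 0)), lf)
  cs3 <- build_correspondences(fixed_lms = lf, moving_lms = lm)
  expect_equal(nrow(cs3$p_fixed), 6L)
  expect_equal(unique(cs3$source), "landmark_center")
  expect_error(build_correspondences(), "no correspondences")
})

test_that("surface and landmark guidance groups share the weight equally", {
  cs <- correspondence_set(matrix(0, 5, 3), matrix(1, 5, 3),
                           c(rep("surface", 3), rep("landmark_center", 2)))
  expect_equal(sum(cs$weight[cs$source == "surface"]), 1 / 2)
  expect_equal(cs$weight[4], 1 / 4)
  expect_equal(sum(cs$weight), 1)
  # a single group takes all the weight
  cs2 <- correspondence_set(matrix(0, 4, 3), matrix(1, 4, 3), "surface")
  expect_equal(cs2$weight, rep(1 / 4, 4))
})

test_that("configuration enforces the complementary 10/90 weighting", {
  cfg <- registration_config()
  expect_equal(cfg$structure_weight, 0.10)
  expect_equal(cfg$intensity_weight, 0.90)
  expect_error(registration_config(structure_weight = 0.2,
                                   intensity_weight = 0.9),
               "must equal 1")
})

test_that("registering an image to itself returns the identity", {
  case <- small_case(1)
  cfg <- small_config(roi = roi_from_mask(case$fixed$mask, 15))
  res <- register_deformable(case$fixed$volume, case$fixed$volume,
                             init = rigid_transform(), config = cfg)
  mag <- sqrt(apply(res$dvf$vectors^2, 1:3, sum))
  expect_lt(max(mag), 0.1)
})

test_that("registration is bit-reproducible for identical inputs", {
  case <- small_case(1)
  cfg <- small_config(roi = roi_from_mask(case$fixed$mask, 15))
  r1 <- register_rigid(case$fixed$volume, case$moving$volume, cfg)
  r2 <- register_rigid(case$fixed$volume, case$moving$volume, cfg)
  expect_identical(r1$translation, r2$translation)
  expect_identical(r1$rotation, r2$rotation)
  d1 <- register_deformable(case$fixed$volume, case$moving$volume, r1, cfg,
                            guidance = structure_guidance(case$fixed$mask,
                                                          case$moving$mask))
  d2 <- register_deformable(case$fixed$volume, case$moving$volume, r2, cfg,
                            guidance = structure_guidance(case$fixed$mask,
                                                          case$moving$mask))
  expect_identical(d1$bspline$coef, d2$bspline$coef)
})

test_that("zero structure weight with guidance reproduces plain DIR", {
  case <- small_case(2)
  cfg0 <- small_config(roi = roi_from_mask(case$fixed$mask, 15))
  rigid <- register_rigid(case$fixed$volume, case$moving$volume, cfg0)
  plain <- register_deformable(case$fixed$volume, case$moving$volume, rigid,
                               cfg0, guidance = NULL)
  cfgw <- small_config(roi = cfg0$roi, structure_weight = 0,
                       intensity_weight = 1)
  guided0 <- register_deformable(case$fixed$volume, case$moving$volume,
                                 rigid, cfgw,
                                 guidance = structure_guidance(
                                   case$fixed$mask, case$moving$mask))
  expect_identical(plain$bspline$coef, guided0$bspline$coef)
})

test_that("structure guidance at a perfect initialization has zero cost", {
  # perfectly aligned structures: correspondence distances vanish at the
  # initial transform
  dim <- c(25, 25, 25)
  g <- grid_geometry(dim, c(2, 2, 2), origin = -(dim - 1))
  r <- sqrt(rowSums(grid_points(g)^2))
  m <- structure_mask(array(as.integer(r <= 15), dim), g, c(s = 1L))
  cs <- build_correspondences(m, m, n_surface_points = 100, seed = 1)
  expect_equal(sum(cs$weight * rowSums((cs$p_fixed - cs$p_moving)^2)), 0)
})
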