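test_that("the phantom pair realizes the requested volume change", {
  case <- default_case(7)
  ratio <- mask_volume_mm3(case$moving$mask) / mask_volume_mm3(case$fixed$mask)
  expect_gte(ratio, 0.80 * 0.98)
  expect_lte(ratio, 0.80 * 1.02)
})

test_that("ground-truth-mapped landmarks coincide exactly with moving ones", {
  case <- default_case(7)
  mapped <- apply_to_points(case$gt$transform, case$fixed$landmarks)
  tre <- target_registration_error(mapped, case$moving$landmarks)
  expect_equal(max(tre$pairs$tre_mm), 0)
})

test_that("the ground-truth Jacobian integrates to the volume change", {
  case <- default_case(7)
  jm <- jacobian_map(case$gt$dvf)
  sel <- mask_indicator(case$fixed$mask) & jm$validity
  expect_lt(abs(mean(jm$values[sel]) - 0.80), 0.03 * 0.80)
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  sp <- small_spec(5)
  a <- make_case(sp)
  b <- make_case(sp)
  expect_identical(a$fixed$volume$voxels, b$fixed$volume$voxels)
  expect_identical(a$moving$volume$voxels, b$moving$volume$voxels)
  expect_identical(a$fixed$landmarks$points, b$fixed$landmarks$points)
  expect_identical(a$gt$dvf$vectors, b$gt$dvf$vectors)
  expect_identical(a$held_out, b$held_out)
})

test_that("CT-like and MRI-like renderings are uncorrelated yet registrable", {
  case <- default_case(7)
  mv_on_fx <- apply_to_volume(case$gt$transform, case$moving$volume,
                              case$fixed$volume$geometry)
  body <- case$fixed$volume$voxels > -500
  expect_lt(abs(cor(case$fixed$volume$voxels[body], mv_on_fx$voxels[body])),
            0.3)
})

test_that("landmark counts follow the 6..11 study convention", {
  cohort <- make_cohort(14, small_spec(1), seed = 3)
  counts <- vapply(cohort, function(cs) nrow(cs$fixed$landmarks$points),
                   integer(1))
  expect_true(all(counts >= 6 & counts <= 11))
  expect_gte(sum(counts), 84)
  expect_lte(sum(counts), 154)
})

test_that("cohorts are reproducible and reduce to make_case per case", {
  c1 <- make_cohort(3, small_spec(1), seed = 9)
  c2 <- make_cohort(3, small_spec(1), seed = 9)
  expect_identical(c1[[2]]$fixed$volume$voxels, c2[[2]]$fixed$volume$voxels)
  expect_identical(c1[[3]]$gt$dvf$vectors, c2[[3]]$gt$dvf$vectors)
  # n = 1 equals make_case on the derived seed
  c3 <- make_cohort(1, small_spec(1), seed = 9)
  set.seed(9)
  derived <- sample.int(2147483646L, 1)
  sp <- small_spec(1); sp$rng_seed <- derived
  direct <- make_case(sp)
  expect_identical(c3[[1]]$fixed$volume$voxels, direct$fixed$volume$voxels)
})

test_that("landmark jitter follows the requested noise model", {
  case <- small_case(2)
  lms <- case$fixed$landmarks
  expect_identical(corrupt_landmarks(lms, 0), lms)
  # RMS of 3-D jitter at sigma = 1 approaches sqrt(3)
  big <- landmark_set(data.frame(name = paste0("P", 1:1000), x = 0, y = 0,
                                 z = 0))
  j <- corrupt_landmarks(big, 1, seed = 4)
  rms <- sqrt(mean(rowSums(as.matrix(j$points[, 2:4])^2)))
  expect_lt(abs(rms - sqrt(3)), 0.05 * sqrt(3))
  j2 <- corrupt_landmarks(big, 1, seed = 5)
  expect_false(identical(j$points, j2$points))
})

test_that("a warp-free full-volume phantom pair aligns under ground truth", {
  sp <- phantom_spec(rng_seed = 3, volume_change_fraction = 1,
                     warp_sd_mm = 0, compression_amplitude_mm = 0,
                     global_shift_mm = 0)
  case <- make_case(sp)
  ratio <- mask_volume_mm3(case$moving$mask) / mask_volume_mm3(case$fixed$mask)
  expect_lt(abs(ratio - 1), 0.02)
  warped <- apply_to_mask(case$gt$transform, case$moving$mask,
                          case$fixed$mask$geometry)
  expect_gte(dice(case$fixed$mask, warped), 0.98)
})

test_that("phantom cases serialize to the package's file formats", {
  case <- small_case(2)
  dir <- file.path(tempdir(), "case_io")
  write_case(case, dir)
  vol <- read_volume(file.path(dir, "fixed_ct.nii.gz"))
  expect_equal(vol$voxels, case$fixed$volume$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
  msk <- read_mask(file.path(dir, "fixed_liver.nii.gz"))
  expect_identical(msk$labels, case$fixed$mask$labels)
  dvf <- read_dvf(file.path(dir, "gt_dvf.nii.gz"))
  expect_equal(dvf$vectors, case$gt$dvf$vectors, tolerance = 1e-6)
  lms <- read_landmarks(file.path(dir, "fixed_landmarks.csv"))
  expect_equal(lms$points$x, case$fixed$landmarks$points$x)
})
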