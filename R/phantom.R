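## ---- phantom specification -----------------------------------------------

#' Specification of a synthetic liver phantom pair
#'
#' Defines the imaging scenario emulated by the phantom generator: a
#' planning-CT-like fixed scan (1.37 x 1.37 x 3 mm grid) and a
#' post-treatment-MRI-like moving scan (0.8 x 0.8 x 2.5 mm grid) of a
#' liver-like organ with internal vessel bifurcation landmarks. The
#' ground-truth inter-scan deformation combines a global volume change
#' (default 20 percent shrinkage of the moving liver), a random smooth
#' B-spline warp, an anterior-posterior compression applied to the fixed
#' image only (emulating an abdominal compression device present at
#' planning), and a small random global shift. The two renderings use
#' deliberately non-monotone intensity class maps so that only mutual
#' information, not correlation, links the modalities.
#'
#' @param fixed_dim,fixed_spacing grid of the CT-like fixed image.
#' @param moving_dim,moving_spacing grid of the MRI-like moving image.
#' @param liver_semiaxes ellipsoid semi-axes of the liver body, mm.
#' @param lobe_amplitude relative amplitude of the lobed boundary
#'   perturbation of the liver surface.
#' @param n_landmarks number of vessel-bifurcation landmarks, or `NULL` to
#'   draw uniformly from 6..11 per case.
#' @param volume_change_fraction moving liver volume / fixed liver volume.
#' @param compression_amplitude_mm peak anterior-posterior compression of
#'   the fixed image.
#' @param warp_control_spacing_mm knot spacing of the random warp.
#' @param warp_sd_mm standard deviation of the random warp coefficients.
#' @param warp_fine_spacing_mm,warp_fine_sd_mm knot spacing and coefficient
#'   SD of an optional second, finer-scale warp component (off by
#'   default); useful for stress-testing registration with deformation
#'   detail below the engine lattice's representable scale.
#' @param global_shift_mm half-width of the uniform random inter-scan
#'   translation per axis.
#' @param ct_levels,mr_levels intensity class levels (air, soft tissue,
#'   liver, vessel) for the two renderings; note the deliberately
#'   different class ordering.
#' @param n_confounders number of liver-isointense adjacent structures
#'   placed against the liver surface (emulating diaphragm/heart/bowel
#'   regions where the organ boundary is invisible to intensity metrics —
#'   the scenario in which contour guidance matters).
#' @param noise_sd_ct,noise_sd_mr additive Gaussian noise per modality.
#' @param psf_sigma_vox Gaussian blur (voxels) applied before noise,
#'   mimicking the scanner point-spread function.
#' @param rng_seed integer seed; the same seed reproduces the phantom pair
#'   bit for bit.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(fixed_dim = c(64, 64, 36),
                         fixed_spacing = c(1.37, 1.37, 3),
                         moving_dim = c(110, 110, 44),
                         moving_spacing = c(0.8, 0.8, 2.5),
                         liver_semiaxes = c(30, 24, 38),
                         lobe_amplitude = 0.12,
                         n_landmarks = NULL,
                         volume_change_fraction = 0.80,
                         compression_amplitude_mm = 8,
                         warp_control_spacing_mm = 40,
                         warp_sd_mm = 5,
                         warp_fine_spacing_mm = 20,
                         warp_fine_sd_mm = 0,
                         global_shift_mm = 5,
                         n_confounders = 3,
                         ct_levels = c(air = -1000, soft = 30, liver = 60,
                                       vessel = 84),
                         mr_levels = c(air = 10, soft = 130, liver = 60,
                                       vessel = 150),
                         noise_sd_ct = 8, noise_sd_mr = 6,
                         psf_sigma_vox = 0.7,
                         rng_seed = 1L) {
  if (volume_change_fraction <= 0 || volume_change_fraction > 1.5)
    stop("volume_change_fraction must lie in (0, 1.5]", call. = FALSE)
  if (!is.null(n_landmarks) && n_landmarks < 3)
    stop("need at least 3 landmarks", call. = FALSE)
  structure(as.list(environment()), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> fixed ", paste(x$fixed_dim, collapse = "x"),
      " @ ", paste(x$fixed_spacing, collapse = "x"), " mm; shrink to ",
      x$volume_change_fraction, "; seed ", x$rng_seed, "\n", sep = "")
  invisible(x)
}

centered_geometry <- function(dm, sp) {
  grid_geometry(dm, sp, origin = -(dm - 1) * sp / 2)
}

## ---- canonical anatomy ---------------------------------------------------

# squared-ellipsoid + lobed perturbation; < 0 inside the liver
liver_implicit <- function(pts, semi, lobe) {
  q <- (pts[, 1] / semi[1])^2 + (pts[, 2] / semi[2])^2 + (pts[, 3] / semi[3])^2
  q - 1 + lobe * sin(0.11 * pts[, 1] + 1.3) *
    sin(0.09 * pts[, 2] - 0.7) * sin(0.07 * pts[, 3] + 0.4)
}

# min distance from each point to a segment set; also used for rendering
dist_to_segments <- function(pts, segs) {
  best <- rep(Inf, nrow(pts))
  for (s in segs) {
    v <- s$b - s$a
    L2 <- sum(v^2)
    w <- sweep(pts, 2, s$a, "-")
    t <- pmin(1, pmax(0, (w %*% v) / L2))
    dx <- w - outer(as.numeric(t), v)
    best <- pmin(best, sqrt(rowSums(dx^2)))
  }
  best
}

# recursive bifurcating vessel tree inside the liver; returns segments and
# the bifurcation points (ends of non-leaf segments)
grow_vessel_tree <- function(start, dir, len, radius, depth, semi, lobe) {
  segs <- list(); bifs <- NULL
  recurse <- function(a, d, l, r, k) {
    b <- a + l * d
    tries <- 0
    while (liver_implicit(rbind(b), semi, lobe) > -0.25 && tries < 5) {
      d <- d - 0.45 * b / sqrt(sum(b^2) + 1e-9)
      d <- d / sqrt(sum(d^2))
      b <- a + l * d
      tries <- tries + 1
    }
    segs[[length(segs) + 1]] <<- list(a = a, b = b, r = r)
    if (k > 0) {
      bifs <<- rbind(bifs, b)
      for (s in 1:2) {
        perp <- rnorm(3)
        perp <- perp - sum(perp * d) * d
        perp <- perp / sqrt(sum(perp^2))
        ang <- runif(1, 0.45, 0.85) * (if (s == 1) 1 else -1)
        nd <- cos(ang) * d + sin(ang) * perp
        recurse(b, nd / sqrt(sum(nd^2)), l * 0.72, r * 0.8, k - 1)
      }
    }
  }
  recurse(start, dir / sqrt(sum(dir^2)), len, radius, depth)
  list(segs = segs, bifs = bifs)
}

## ---- phantom case --------------------------------------------------------

#' Generate one synthetic phantom case
#'
#' Builds the paired CT-like / MRI-like volumes, liver masks, vessel
#' bifurcation landmarks, and the ground-truth transform and displacement
#' field relating them. The global scale of the ground-truth deformation is
#' calibrated so that the rendered liver pair realizes the requested volume
#' change fraction. Random warps whose Jacobian drops below 0.25 anywhere
#' in the liver are rejected and redrawn (up to 5 attempts).
#'
#' @param spec a [phantom_spec].
#' @return A `phantom_case` with elements `fixed` and `moving` (each:
#'   `volume`, `mask`, `landmarks`), `gt` (`transform`, `dvf`,
#'   `scale`), `held_out` (names of the held-out landmark subset), `spec`.
#' @export
make_case <- function(spec) {
  set.seed(spec$rng_seed)
  semi <- spec$liver_semiaxes
  lobe <- spec$lobe_amplitude
  fixed_geom <- centered_geometry(spec$fixed_dim, spec$fixed_spacing)
  moving_geom <- centered_geometry(spec$moving_dim, spec$moving_spacing)
  fov_half <- (spec$fixed_dim - 1) * spec$fixed_spacing / 2

  ## vessel trees in the canonical frame (two trees, depth 3 -> up to 14
  ## bifurcations)
  t1 <- grow_vessel_tree(c(-0.35, 0.1, -0.45) * semi, c(0.55, -0.2, 1),
                         0.45 * semi[3], 4.5, 3, semi, lobe)
  t2 <- grow_vessel_tree(c(0.4, -0.15, 0.5) * semi, c(-0.5, 0.3, -1),
                         0.4 * semi[3], 4, 3, semi, lobe)
  segs <- c(t1$segs, t2$segs)
  bifs <- rbind(t1$bifs, t2$bifs)

  ## liver-isointense structures resting against the organ surface; their
  ## shared boundary with the liver is invisible to intensity similarity
  confounders <- list()
  if (spec$n_confounders > 0) {
    for (i in seq_len(spec$n_confounders)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      r_surf <- 1 / sqrt(sum((u / semi)^2))
      br <- runif(3, 11, 19)
      confounders[[i]] <- list(center = u * (r_surf + 0.45 * mean(br)),
                               semi = br)
    }
  }

  n_lm <- if (is.null(spec$n_landmarks)) sample(6:11, 1) else spec$n_landmarks
  inside <- liver_implicit(bifs, semi, lobe) < -0.2
  cand <- bifs[inside, , drop = FALSE]
  if (nrow(cand) < n_lm) {    # fall back to mid-segment points if needed
    mids <- t(vapply(segs, function(s) (s$a + s$b) / 2, numeric(3)))
    mids <- mids[liver_implicit(mids, semi, lobe) < -0.2, , drop = FALSE]
    cand <- rbind(cand, mids)
  }
  if (nrow(cand) < n_lm) n_lm <- nrow(cand)
  lm_canon <- cand[sample(nrow(cand), n_lm), , drop = FALSE]

  ## anatomy class in the canonical frame:
  ## 0 air, 1 soft tissue, 2 liver, 3 vessel, 4 liver-isointense neighbour
  body_semi <- semi * 1.45 + 12
  class_at <- function(pts) {
    cls <- integer(nrow(pts))
    body <- (pts[, 1] / body_semi[1])^2 + (pts[, 2] / body_semi[2])^2 +
      (pts[, 3] / body_semi[3])^2 < 1
    liv <- liver_implicit(pts, semi, lobe) < 0
    cls[body] <- 1L
    for (cf in confounders) {
      d <- sweep(pts, 2, cf$center, "-")
      inb <- (d[, 1] / cf$semi[1])^2 + (d[, 2] / cf$semi[2])^2 +
        (d[, 3] / cf$semi[3])^2 < 1
      cls[inb & body & !liv] <- 4L
    }
    cls[liv] <- 2L
    if (any(liv)) {
      dv <- dist_to_segments(pts[liv, , drop = FALSE], segs)
      cls[which(liv)[dv < 4.2]] <- 3L   # effective vessel radius, mm
    }
    cls
  }
  liver_at <- function(pts) liver_implicit(pts, semi, lobe) < 0

  ## fixed-image compression (anterior-posterior, along +y), analytic
  amp <- spec$compression_amplitude_mm
  comp_disp <- function(pts) {
    u <- matrix(0, nrow(pts), 3)
    if (amp > 0) {
      bell <- exp(-(pts[, 1]^2 + (pts[, 3] / 1.5)^2) / 55^2)
      front <- exp(-((pts[, 2] + body_semi[2]) / 40)^2)
      u[, 2] <- amp * bell * front
    }
    u
  }
  phi <- function(pts) pts + comp_disp(pts)          # fixed -> canonical
  phi_inv <- function(pts) {
    x <- pts
    for (i in 1:30) x <- pts - comp_disp(x)
    x
  }

  ## random smooth multi-scale warp in the canonical frame (a coarse and a
  ## fine B-spline component), redrawn if the composite folds
  dom <- rbind(-fov_half - 25, fov_half + 25)
  warp <- NULL
  probe <- as.matrix(expand.grid(
    x = seq(-semi[1], semi[1], length.out = 9),
    y = seq(-semi[2], semi[2], length.out = 9),
    z = seq(-semi[3], semi[3], length.out = 9)))
  for (try in 1:5) {
    w1 <- bspline_transform(dom, spec$warp_control_spacing_mm)
    w1$coef[] <- rnorm(length(w1$coef), sd = spec$warp_sd_mm)
    w2 <- bspline_transform(dom, spec$warp_fine_spacing_mm)
    w2$coef[] <- rnorm(length(w2$coef), sd = spec$warp_fine_sd_mm)
    j1 <- bspline_displacement(w1, probe, jacobian = TRUE, strict = FALSE)
    j2 <- bspline_displacement(w2, probe, jacobian = TRUE, strict = FALSE)
    dets <- vapply(seq_len(nrow(probe)), function(i)
      det(diag(3) + matrix(j1$jac[i, ] + j2$jac[i, ], 3, 3)), numeric(1))
    if (min(dets) > 0.25) { warp <- list(w1, w2); break }
  }
  if (is.null(warp))
    stop("could not draw a fold-free warp in 5 attempts; reduce warp_sd_mm",
         call. = FALSE)
  shift <- runif(3, -spec$global_shift_mm, spec$global_shift_mm)

  warp_disp <- function(pts) {
    bspline_displacement(warp[[1]], pts, strict = FALSE)$disp +
      bspline_displacement(warp[[2]], pts, strict = FALSE)$disp
  }
  warp_fun <- function(pts) pts + warp_disp(pts)
  warp_inv <- function(pts) {
    x <- pts
    for (i in 1:12) x <- pts - warp_disp(x)
    x
  }

  ## render the fixed (CT-like) image and mask
  fx_pts <- grid_points(fixed_geom)
  fx_canon <- phi(fx_pts)
  fx_cls <- class_at(fx_canon)
  fx_liver <- array(liver_at(fx_canon), fixed_geom$dim)
  ct_map <- c(spec$ct_levels, spec$ct_levels[["liver"]])   # class 4 isointense
  ct_int <- array(ct_map[fx_cls + 1L], fixed_geom$dim)
  v_fixed <- sum(fx_liver) * prod(fixed_geom$spacing)

  ## calibrate the global scale so that the realized liver volume ratio is
  ## the requested volume change fraction
  canon_step <- 1.5
  cg <- as.matrix(expand.grid(
    x = seq(-semi[1] - 3, semi[1] + 3, by = canon_step),
    y = seq(-semi[2] - 3, semi[2] + 3, by = canon_step),
    z = seq(-semi[3] - 3, semi[3] + 3, by = canon_step)))
  cin <- liver_at(cg)
  jw1 <- bspline_displacement(warp[[1]], cg[cin, , drop = FALSE],
                              jacobian = TRUE, strict = FALSE)
  jw2 <- bspline_displacement(warp[[2]], cg[cin, , drop = FALSE],
                              jacobian = TRUE, strict = FALSE)
  detw <- vapply(seq_len(sum(cin)), function(i)
    det(diag(3) + matrix(jw1$jac[i, ] + jw2$jac[i, ], 3, 3)), numeric(1))
  v_canon_warped <- sum(cin) * canon_step^3 * mean(detw)
  s_scale <- (spec$volume_change_fraction * v_fixed / v_canon_warped)^(1 / 3)

  psi <- function(pts) {            # canonical -> moving
    w <- warp_fun(pts)
    sweep(s_scale * w, 2, shift, "+")
  }
  psi_inv <- function(pts) {
    warp_inv(sweep(pts, 2, shift, "-") / s_scale)
  }
  gt_fun <- function(pts) psi(phi(rbind(pts)))   # fixed -> moving

  ## render the moving (MRI-like) image and mask
  mv_pts <- grid_points(moving_geom)
  mv_canon <- psi_inv(mv_pts)
  mv_cls <- class_at(mv_canon)
  mv_liver <- array(liver_at(mv_canon), moving_geom$dim)
  mr_map <- c(spec$mr_levels, spec$mr_levels[["liver"]])
  mr_int <- array(mr_map[mv_cls + 1L], moving_geom$dim)

  blur_noise <- function(arr, geom, sdv) {
    a <- cpp_smooth3d(as.numeric(arr), geom$dim, rep(spec$psf_sigma_vox, 3))
    array(a + rnorm(length(a), sd = sdv), geom$dim)
  }
  fixed_vol <- image_volume(blur_noise(ct_int, fixed_geom, spec$noise_sd_ct),
                            fixed_geom$spacing, fixed_geom$origin)
  moving_vol <- image_volume(blur_noise(mr_int, moving_geom, spec$noise_sd_mr),
                             moving_geom$spacing, moving_geom$origin)

  fixed_mask <- structure_mask(array(as.integer(fx_liver), fixed_geom$dim),
                               fixed_geom, c(liver = 1L))
  moving_mask <- structure_mask(array(as.integer(mv_liver), moving_geom$dim),
                                moving_geom, c(liver = 1L))

  ## landmarks: canonical bifurcations pulled back into each frame;
  ## moving landmarks are exactly the ground truth image of the fixed ones
  lm_names <- paste0("L", seq_len(n_lm))
  fx_lm <- phi_inv(lm_canon)
  mv_lm <- gt_fun(fx_lm)
  fixed_lms <- landmark_set(data.frame(name = lm_names, x = fx_lm[, 1],
                                       y = fx_lm[, 2], z = fx_lm[, 3]),
                            frame = "fixed")
  moving_lms <- landmark_set(data.frame(name = lm_names, x = mv_lm[, 1],
                                        y = mv_lm[, 2], z = mv_lm[, 3]),
                             frame = "moving")
  held_out <- sort(sample(lm_names, floor(n_lm / 2)))

  gt_dvf <- to_displacement_field(gt_fun, fixed_geom)

  structure(list(
    fixed = list(volume = fixed_vol, mask = fixed_mask, landmarks = fixed_lms),
    moving = list(volume = moving_vol, mask = moving_mask,
                  landmarks = moving_lms),
    gt = list(transform = gt_fun, dvf = gt_dvf, scale = s_scale,
              shift = shift),
    held_out = held_out,
    spec = spec), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> ", nrow(x$fixed$landmarks$points), " landmarks; ",
      "liver ", round(mask_volume_mm3(x$fixed$mask) / 1000, 1), " cm^3 -> ",
      round(mask_volume_mm3(x$moving$mask) / 1000, 1), " cm^3\n", sep = "")
  invisible(x)
}

#' Jitter landmark positions
#'
#' Adds isotropic Gaussian noise to each landmark, modelling observer
#' localization error. `sigma_mm = 0` returns the input unchanged.
#'
#' @param lms a [landmark_set].
#' @param sigma_mm per-axis standard deviation, mm.
#' @param seed integer seed.
#' @return A jittered [landmark_set].
#' @export
corrupt_landmarks <- function(lms, sigma_mm, seed = 1L) {
  stopifnot(sigma_mm >= 0)
  if (sigma_mm == 0) return(lms)
  set.seed(seed)
  m <- landmark_matrix(lms)
  m <- m + matrix(rnorm(length(m), sd = sigma_mm), ncol = 3)
  out <- lms
  out$points[, c("x", "y", "z")] <- m
  out
}

#' Generate a seeded phantom cohort
#'
#' Derives one reproducible sub-seed per case from `seed`; each case varies
#' in its random warp, global shift, vessel tree and landmark count.
#'
#' @param n_cases number of cases (>= 1).
#' @param base_spec a [phantom_spec]; its `rng_seed` is replaced per case.
#' @param seed cohort master seed.
#' @return list of `phantom_case`s.
#' @export
make_cohort <- function(n_cases, base_spec = phantom_spec(), seed = 1L) {
  stopifnot(n_cases >= 1)
  set.seed(seed)
  case_seeds <- sample.int(2147483646L, n_cases)
  lapply(case_seeds, function(s) {
    sp <- base_spec
    sp$rng_seed <- s
    make_case(sp)
  })
}

#' Write a phantom case to disk in the package's file formats
#'
#' Writes NIfTI volumes and masks, the ground-truth displacement field with
#' its YAML sidecar, and CSV landmark files into a directory.
#'
#' @param case a `phantom_case`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(case$fixed$volume, file.path(dir, "fixed_ct.nii.gz"))
  write_volume(case$moving$volume, file.path(dir, "moving_mr.nii.gz"))
  write_mask(case$fixed$mask, file.path(dir, "fixed_liver.nii.gz"))
  write_mask(case$moving$mask, file.path(dir, "moving_liver.nii.gz"))
  write_dvf(case$gt$dvf, file.path(dir, "gt_dvf.nii.gz"))
  write_landmarks(case$fixed$landmarks, file.path(dir, "fixed_landmarks.csv"))
  write_landmarks(case$moving$landmarks, file.path(dir, "moving_landmarks.csv"))
  invisible(dir)
}
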