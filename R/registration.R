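## ---- configuration -------------------------------------------------------

#' Registration configuration
#'
#' Settings shared by the rigid and deformable engines. The default
#' structure/intensity split is 10/90: ten percent of the cost weight is
#' carried by the structure-correspondence term, ninety percent by
#' normalized mutual information.
#'
#' @param roi physical bounding box (2 x 3 matrix, mm) restricting the
#'   similarity metric; `NULL` means the whole fixed image. Typically the
#'   liver bounding box padded by 20 mm, see [roi_from_mask()].
#' @param pyramid_levels number of multi-resolution levels (>= 1); level
#'   `l` works on images smoothed and downsampled by `2^(l-1)`.
#' @param histogram_bins joint histogram size per axis.
#' @param structure_weight,intensity_weight cost weights; must sum to 1.
#' @param optimizer `"lbfgs"` or `"gradient_descent"`.
#' @param max_iters optimizer iterations per level.
#' @param convergence_tol relative cost-change tolerance.
#' @param bending_energy_weight coefficient-roughness regularizer (sum of
#'   squared second differences of the control lattice). The small default
#'   pins down lattice regions the image data cannot constrain (uniform
#'   organ interior, out-of-ROI corners), where an unregularized fit
#'   drifts by exploiting histogram sharpening; it is far too weak to
#'   suppress genuine folding, which remains observable in the Jacobian
#'   analysis. Set to 0 for a fully unregularized fit.
#' @param control_spacing_mm B-spline knot spacing.
#' @param n_surface_points surface correspondences sampled per outer
#'   iteration.
#' @param outer_iterations correspondence re-estimation rounds per level.
#' @param max_samples cap on the number of ROI voxels entering the joint
#'   histogram per level (a seeded uniform subsample is used above it).
#' @param rng_seed seed for the stochastic steps (ROI sampling jitter,
#'   surface sampling).
#' @return A `registration_config` list.
#' @export
registration_config <- function(roi = NULL, pyramid_levels = 3L,
                                histogram_bins = 64L,
                                structure_weight = 0.10,
                                intensity_weight = 0.90,
                                optimizer = c("lbfgs", "gradient_descent"),
                                max_iters = 100L, convergence_tol = 1e-5,
                                bending_energy_weight = 2e-4,
                                control_spacing_mm = 30,
                                n_surface_points = 400L,
                                outer_iterations = 3L,
                                max_samples = 25000L,
                                rng_seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (abs(structure_weight + intensity_weight - 1) > 1e-9)
    stop("structure_weight + intensity_weight must equal 1", call. = FALSE)
  structure(as.list(environment()), class = "registration_config")
}

#' Region of interest from a structure mask
#'
#' Physical bounding box of the labelled voxels, padded on every side —
#' the deformable ROI is chosen large enough to encompass the entire
#' structure.
#'
#' @param mask a [structure_mask].
#' @param pad_mm padding, mm (default 20).
#' @param label label value or name.
#' @return 2 x 3 matrix (rows: lower, upper corner, mm).
#' @export
roi_from_mask <- function(mask, pad_mm = 20, label = mask$label_names[[1]]) {
  idx <- which(mask_indicator(mask, label), arr.ind = TRUE) - 1
  if (nrow(idx) == 0) stop("empty mask: no ROI", call. = FALSE)
  w <- voxel_to_world(mask$geometry, idx)
  rbind(apply(w, 2, min) - pad_mm, apply(w, 2, max) + pad_mm)
}

## ---- normalized mutual information (reporting form) ----------------------

bin_values <- function(v, nbins, lo = min(v), hi = max(v)) {
  if (hi - lo <= 0)
    stop("degenerate NMI: image is constant inside the ROI", call. = FALSE)
  b <- floor((v - lo) / (hi - lo) * nbins)
  as.integer(pmin(pmax(b, 0), nbins - 1))
}

entropy_from_counts <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log(p))
}

#' Normalized mutual information of two images
#'
#' `NMI = (H(F) + H(M)) / H(F, M)` from a hard-binned joint histogram over
#' the ROI voxels; lies in (1, 2], reaching 2 for identical non-constant
#' images. Symmetric in its arguments.
#'
#' @param fixed,warped_moving [image_volume]s on the same grid.
#' @param roi_mask optional [structure_mask] (or logical array) selecting
#'   the voxels entering the histogram.
#' @param bins histogram bins per intensity axis.
#' @return NMI scalar.
#' @export
nmi <- function(fixed, warped_moving, roi_mask = NULL, bins = 64L) {
  if (!same_geometry(fixed$geometry, warped_moving$geometry))
    stop("images must share a grid", call. = FALSE)
  sel <- if (is.null(roi_mask)) TRUE
         else if (inherits(roi_mask, "structure_mask")) mask_indicator(roi_mask)
         else roi_mask
  f <- fixed$voxels[sel]; m <- warped_moving$voxels[sel]
  if (length(f) == 0) stop("empty ROI", call. = FALSE)
  fb <- bin_values(f, bins); mb <- bin_values(m, bins)
  joint <- unclass(table(factor(fb, levels = 0:(bins - 1)),
                         factor(mb, levels = 0:(bins - 1))))
  hf <- entropy_from_counts(rowSums(joint))
  hm <- entropy_from_counts(colSums(joint))
  hj <- entropy_from_counts(as.numeric(joint))
  (hf + hm) / hj
}

## ---- pyramid helpers -----------------------------------------------------

# Gaussian-smooth and downsample a volume by an integer factor
downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  g <- vol$geometry
  sm <- array(cpp_smooth3d(as.numeric(vol$voxels), g$dim,
                           rep(0.5 * factor, 3)), g$dim)
  new_dim <- pmax(4L, as.integer(ceiling(g$dim / factor)))
  new_geom <- grid_geometry(new_dim, g$spacing * factor, g$origin,
                            g$orientation)
  smv <- image_volume(sm, g$spacing, g$origin, g$orientation)
  apply_to_volume(rigid_transform(), smv, new_geom, "linear")
}

# fixed-image ROI sample: world points and intensity bins at one level.
# Sample positions are jittered off-grid (up to ~half a voxel, seeded) to
# break the grid-alignment artifact of histogram similarity metrics, which
# otherwise creates a spurious optimum whenever the two voxel lattices
# coincide exactly.
roi_sample <- function(vol, roi, nbins, jitter_seed = 1L,
                       max_samples = Inf) {
  pts <- grid_points(vol$geometry)
  sel <- rep(TRUE, nrow(pts))
  if (!is.null(roi)) {
    for (a in 1:3) sel <- sel & pts[, a] >= roi[1, a] & pts[, a] <= roi[2, a]
  }
  if (sum(sel) < 64) stop("ROI contains too few voxels", call. = FALSE)
  pts <- pts[sel, , drop = FALSE]
  set.seed(jitter_seed)
  if (nrow(pts) > max_samples)
    pts <- pts[sort(sample.int(nrow(pts), max_samples)), , drop = FALSE]
  jit <- (matrix(runif(length(pts)), ncol = 3) - 0.5) * 0.9
  pts <- pts + jit %*% (vol$geometry$orientation %*%
                          diag(vol$geometry$spacing))
  s <- cpp_sample_volume(as.numeric(vol$voxels), vol$geometry$dim,
                         w2v_matrix(vol$geometry), pts, 0L, 0)
  keep <- s$inside
  list(pts = pts[keep, , drop = FALSE],
       bins = bin_values(s$values[keep], nbins))
}

rigid_from_params <- function(p, center) {
  out <- rigid_transform(p[1:3], p[4:6], center)
  out
}

## ---- rigid registration --------------------------------------------------

#' Rigid registration by normalized mutual information
#'
#' Finds the six-degree-of-freedom transform (translation + Euler ZYX
#' rotation about the ROI centroid) maximizing NMI between the fixed image
#' and the resampled moving image, over a multi-resolution pyramid. The
#' NMI inside the optimizer uses partial-volume interpolation of the
#' moving histogram so the cost is continuous in the parameters.
#' Deterministic for a fixed configuration.
#'
#' @param fixed,moving [image_volume]s with overlapping physical extents.
#' @param config a [registration_config].
#' @return A [rigid_transform] with attribute `"diagnostics"` (per-level
#'   cost traces and final NMI).
#' @export
register_rigid <- function(fixed, moving, config = registration_config()) {
  roi <- config$roi
  nbins <- config$histogram_bins
  factors <- 2^((config$pyramid_levels:1) - 1)
  center <- if (is.null(roi)) {
    colMeans(voxel_to_world(fixed$geometry,
                            rbind(c(0, 0, 0), fixed$geometry$dim - 1)))
  } else colMeans(roi)
  # center-of-mass initialization: align the binarized body masses so the
  # NMI optimization starts inside its capture basin
  body_centroid <- function(vol) {
    v <- as.numeric(vol$voxels)
    w <- v > min(v) + 0.25 * (max(v) - min(v))
    colSums(grid_points(vol$geometry)[w, , drop = FALSE]) / sum(w)
  }
  par <- c(body_centroid(moving) - body_centroid(fixed), 0, 0, 0)
  diag_list <- list()
  for (f in factors) {
    fl <- downsample_volume(fixed, f)
    ml <- downsample_volume(moving, f)
    rs <- roi_sample(fl, roi, nbins, config$rng_seed, config$max_samples)
    mb <- array(bin_values(as.numeric(ml$voxels), nbins), ml$geometry$dim)
    w2v <- w2v_matrix(ml$geometry)
    cost <- function(p) {
      tr <- rigid_from_params(p, center)
      base <- transform_points_matrix(tr, rs$pts)
      r <- cpp_nmi_pv(base, rs$bins, numeric(0), c(0L, 0L, 0L), numeric(3),
                      rep(1, 3), as.integer(mb), ml$geometry$dim, w2v,
                      nbins, 0L)
      if (is.na(r$cost)) return(0)   # lost overlap: worst possible cost
      r$cost
    }
    h <- c(rep(0.25 * f, 3), rep(0.0025 * f, 3))
    grad <- function(p) {
      vapply(1:6, function(i) {
        e <- numeric(6); e[i] <- h[i]
        (cost(p + e) - cost(p - e)) / (2 * h[i])
      }, numeric(1))
    }
    opt <- optim(par, cost, grad, method = "L-BFGS-B",
                 control = list(maxit = config$max_iters,
                                factr = config$convergence_tol /
                                  .Machine$double.eps))
    if (!is.finite(opt$value))
      stop("rigid registration diverged (non-finite cost); parameters: ",
           paste(signif(opt$par, 4), collapse = ", "), call. = FALSE)
    par <- opt$par
    diag_list[[length(diag_list) + 1]] <-
      list(factor = f, cost = opt$value, convergence = opt$convergence)
  }
  out <- rigid_from_params(par, center)
  attr(out, "diagnostics") <- list(levels = diag_list, final_nmi = -diag_list[[length(diag_list)]]$cost)
  out
}

## ---- correspondences -----------------------------------------------------

#' Structure and landmark correspondence pairs
#'
#' The correspondence cost balances its two guidance groups: the surface
#' point cloud of the guided structure and the set of overlaid landmark
#' centers each carry half of the total weight when both are present
#' (all of it otherwise); pairs share their group's weight equally.
#' `weight` holds the resulting per-pair weights, normalized to sum to 1.
#'
#' @param p_fixed,p_moving n x 3 matrices of paired points, mm (fixed
#'   frame / moving frame).
#' @param source character vector: `"surface"` or `"landmark_center"`.
#' @param weight optional per-pair weights (renormalized); by default the
#'   per-group scheme above.
#' @return A `correspondence_set`.
#' @export
correspondence_set <- function(p_fixed, p_moving, source, weight = NULL,
                               normals = NULL) {
  p_fixed <- rbind(p_fixed); p_moving <- rbind(p_moving)
  stopifnot(nrow(p_fixed) == nrow(p_moving),
            all(is.finite(p_fixed)), all(is.finite(p_moving)))
  source <- rep_len(source, nrow(p_fixed))
  if (is.null(weight)) {
    n_surf <- sum(source == "surface")
    n_lm <- sum(source != "surface")
    n_groups <- (n_surf > 0) + (n_lm > 0)
    weight <- ifelse(source == "surface", 1 / max(n_surf, 1),
                     1 / max(n_lm, 1)) / n_groups
  }
  weight <- weight / sum(weight)
  if (is.null(normals)) normals <- matrix(NA_real_, nrow(p_fixed), 3)
  structure(list(p_fixed = p_fixed, p_moving = p_moving,
                 source = source, weight = weight, normals = rbind(normals)),
            class = "correspondence_set")
}

#' @export
print.correspondence_set <- function(x, ...) {
  cat("<correspondence_set> ", nrow(x$p_fixed), " pairs (",
      sum(x$source == "surface"), " surface, ",
      sum(x$source == "landmark_center"), " landmark)\n", sep = "")
  invisible(x)
}

# outward surface normals of a mask, estimated from the gradient of the
# smoothed indicator, evaluated at given surface points (mm coordinates)
surface_normals <- function(mask, pts, label = mask$label_names[[1]]) {
  g <- mask$geometry
  ind <- array(as.numeric(mask_indicator(mask, label)), g$dim)
  sm <- array(cpp_smooth3d(as.numeric(ind), g$dim, c(1.2, 1.2, 1.2)), g$dim)
  idx <- round(world_to_voxel(g, pts)) + 1
  idx[, 1] <- pmin(pmax(idx[, 1], 2), g$dim[1] - 1)
  idx[, 2] <- pmin(pmax(idx[, 2], 2), g$dim[2] - 1)
  idx[, 3] <- pmin(pmax(idx[, 3], 2), g$dim[3] - 1)
  li <- function(di) (idx[, 1] + di[1]) +
    g$dim[1] * ((idx[, 2] + di[2] - 1) + g$dim[2] * (idx[, 3] + di[3] - 1))
  gv <- cbind((sm[li(c(1, 0, 0))] - sm[li(c(-1, 0, 0))]) / (2 * g$spacing[1]),
              (sm[li(c(0, 1, 0))] - sm[li(c(0, -1, 0))]) / (2 * g$spacing[2]),
              (sm[li(c(0, 0, 1))] - sm[li(c(0, 0, -1))]) / (2 * g$spacing[3]))
  # gradient in index axes -> world axes
  gv <- gv %*% t(g$orientation)
  nrm <- sqrt(rowSums(gv^2))
  nrm[nrm < 1e-12] <- 1
  -gv / nrm   # outward: indicator decreases outward, gradient points inward
}

# index of the nearest row of `to` for each row of `from` (chunked)
nearest_index <- function(from, to) {
  t2 <- rowSums(to^2)
  out <- integer(nrow(from))
  step <- 256L
  for (s in seq(1, nrow(from), by = step)) {
    e <- min(s + step - 1L, nrow(from))
    blk <- from[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), t2, "+") - 2 * blk %*% t(to)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Build structure/landmark correspondences
#'
#' Surface pairs: `n_surface_points` points sampled uniformly from the
#' moving structure's surface, each matched to the nearest fixed-surface
#' point (after mapping the fixed surface through `transform`, so pairs can
#' be re-estimated as a registration progresses, ICP-style). Landmark
#' pairs: exact name-matched point pairs. The union is returned.
#'
#' @param fixed_mask,moving_mask [structure_mask]s (surface guidance;
#'   either may be `NULL` for landmark-only guidance).
#' @param fixed_lms,moving_lms optional paired [landmark_set]s.
#' @param n_surface_points number of surface samples.
#' @param transform current fixed-to-moving estimate (default identity).
#' @param seed sampling seed.
#' @return A [correspondence_set].
#' @export
build_correspondences <- function(fixed_mask = NULL, moving_mask = NULL,
                                  fixed_lms = NULL, moving_lms = NULL,
                                  n_surface_points = 400L,
                                  transform = rigid_transform(),
                                  seed = 1L) {
  pf <- NULL; pm <- NULL; src <- character(0); nrm <- NULL
  if (!is.null(fixed_mask) && !is.null(moving_mask)) {
    sf <- surface_points(fixed_mask)
    sm <- surface_points(moving_mask)
    set.seed(seed)
    take <- if (nrow(sm) > n_surface_points)
      sort(sample.int(nrow(sm), n_surface_points)) else seq_len(nrow(sm))
    smp <- sm[take, , drop = FALSE]
    wf <- transform_points_matrix(transform, sf)
    ni <- nearest_index(smp, wf)
    pf <- sf[ni, , drop = FALSE]
    pm <- smp
    src <- rep("surface", nrow(pf))
    # moving-surface normals: the optimizer penalizes only the normal
    # component of surface residuals (point-to-plane), avoiding the
    # tangential drag of raw nearest-neighbour pairing
    nrm <- surface_normals(moving_mask, smp)
  }
  if (!is.null(fixed_lms) && !is.null(moving_lms)) {
    pr <- pair_landmarks(fixed_lms, moving_lms)
    pf <- rbind(pf, pr$a)
    pm <- rbind(pm, pr$b)
    src <- c(src, rep("landmark_center", length(pr$names)))
    nrm <- rbind(nrm, matrix(NA_real_, length(pr$names), 3))
  }
  if (is.null(pf) || nrow(pf) == 0)
    stop("no correspondences: supply masks and/or paired landmarks",
         call. = FALSE)
  correspondence_set(pf, pm, src, normals = nrm)
}

#' Guidance inputs for structure-guided registration
#'
#' Bundles the masks and landmark sets from which correspondences are
#' re-estimated during registration.
#'
#' @inheritParams build_correspondences
#' @return A `structure_guidance` object.
#' @export
structure_guidance <- function(fixed_mask = NULL, moving_mask = NULL,
                               fixed_lms = NULL, moving_lms = NULL) {
  if (is.null(fixed_mask) && is.null(fixed_lms))
    stop("guidance needs masks and/or landmarks", call. = FALSE)
  structure(list(fixed_mask = fixed_mask, moving_mask = moving_mask,
                 fixed_lms = fixed_lms, moving_lms = moving_lms),
            class = "structure_guidance")
}

## ---- deformable registration ---------------------------------------------

# sparse basis matrix mapping control coefficients to displacements at pts
basis_matrix <- function(tr, pts) {
  b <- cpp_bspline_basis(tr$lattice_dim, tr$lattice_origin,
                         tr$control_spacing, pts)
  keep <- which(b$inside)
  n <- length(keep)
  ncp <- prod(tr$lattice_dim)
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 64),
    j = as.integer(b$idx[keep, , drop = FALSE]) + 1L,
    x = as.numeric(b$w[keep, , drop = FALSE]),
    dims = c(n, ncp))
  list(M = M, keep = keep)
}

# second-difference roughness of the coefficient lattice and its gradient
bending_penalty <- function(coef_mat, cdim) {
  ncp <- prod(cdim)
  pen <- 0
  grad <- matrix(0, ncp, 3)
  arr <- array(coef_mat, c(cdim, 3))
  for (ax in 1:3) {
    n <- cdim[ax]
    if (n < 3) next
    idx <- function(k) {
      if (ax == 1) arr[k, , , , drop = FALSE]
      else if (ax == 2) arr[, k, , , drop = FALSE]
      else arr[, , k, , drop = FALSE]
    }
    d2 <- idx(3:n) - 2 * idx(2:(n - 1)) + idx(1:(n - 2))
    pen <- pen + sum(d2^2)
    gadd <- array(0, c(cdim, 3))
    if (ax == 1) {
      gadd[1:(n - 2), , , ] <- gadd[1:(n - 2), , , ] + 2 * d2
      gadd[2:(n - 1), , , ] <- gadd[2:(n - 1), , , ] - 4 * d2
      gadd[3:n, , , ] <- gadd[3:n, , , ] + 2 * d2
    } else if (ax == 2) {
      gadd[, 1:(n - 2), , ] <- gadd[, 1:(n - 2), , ] + 2 * d2
      gadd[, 2:(n - 1), , ] <- gadd[, 2:(n - 1), , ] - 4 * d2
      gadd[, 3:n, , ] <- gadd[, 3:n, , ] + 2 * d2
    } else {
      gadd[, , 1:(n - 2), ] <- gadd[, , 1:(n - 2), ] + 2 * d2
      gadd[, , 2:(n - 1), ] <- gadd[, , 2:(n - 1), ] - 4 * d2
      gadd[, , 3:n, ] <- gadd[, , 3:n, ] + 2 * d2
    }
    grad <- grad + matrix(gadd, ncp, 3)
  }
  list(value = pen, grad = grad)
}

# simple backtracking gradient descent (the non-default optimizer)
descend <- function(par, fn, gr, maxit, tol) {
  f <- fn(par)
  step <- 1
  for (it in seq_len(maxit)) {
    g <- gr(par)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    ok <- FALSE
    for (k in 1:20) {
      cand <- par - step * g
      fc <- fn(cand)
      if (is.finite(fc) && fc < f) { ok <- TRUE; break }
      step <- step / 2
    }
    if (!ok) break
    if (abs(f - fc) < tol * abs(f)) { par <- cand; f <- fc; break }
    par <- cand; f <- fc; step <- step * 1.5
  }
  list(par = par, value = f)
}

#' B-spline deformable registration (plain and structure-guided)
#'
#' Minimizes `C = intensity_weight * C_NMI + structure_weight * C_struct`
#' over the coefficients of a cubic B-spline free-form deformation applied
#' on top of a rigid baseline, where `C_NMI = -NMI` (partial-volume joint
#' histogram) and `C_struct` is the mean squared distance (mm^2) of the
#' structure/landmark correspondence pairs. Each term is scale-normalized
#' by its magnitude at the level's starting transform so the 10/90 weights
#' act on relative improvements. With `guidance = NULL` the structure term
#' is absent and the method reduces to plain intensity-driven deformable
#' registration. Surface correspondences are re-estimated from the masks
#' each outer iteration; landmark pairs stay fixed.
#'
#' @param fixed,moving [image_volume]s.
#' @param init rigid baseline (from [register_rigid]); identity if `NULL`.
#' @param config a [registration_config].
#' @param guidance `NULL`, a static [correspondence_set], or a
#'   [structure_guidance] bundle (correspondences then re-estimated).
#' @return An `sgdir_registration`: `transform` (the composite fixed-to-
#'   moving map), `bspline` (the fitted [bspline_transform]), `rigid_init`,
#'   `dvf` (the transform sampled on the fixed grid), `diagnostics`.
#' @export
register_deformable <- function(fixed, moving, init = NULL,
                                config = registration_config(),
                                guidance = NULL) {
  if (is.null(init)) init <- rigid_transform()
  roi <- config$roi
  if (is.null(roi))
    roi <- rbind(apply(grid_points(fixed$geometry), 2, min),
                 apply(grid_points(fixed$geometry), 2, max))
  nbins <- config$histogram_bins
  wI <- config$intensity_weight
  wS <- config$structure_weight
  has_guidance <- !is.null(guidance)
  if (!has_guidance) { wI <- 1; wS <- 0 }
  if (has_guidance && wS > 0 && inherits(guidance, "correspondence_set") &&
      nrow(guidance$p_fixed) == 0)
    stop("empty guidance with structure_weight > 0", call. = FALSE)

  pad <- config$control_spacing_mm + 15
  dom <- rbind(roi[1, ] - pad, roi[2, ] + pad)
  ffd <- bspline_transform(dom, config$control_spacing_mm)
  cdim <- ffd$lattice_dim
  ncp <- prod(cdim)
  par <- numeric(ncp * 3)

  factors <- 2^((config$pyramid_levels:1) - 1)
  trace <- list()
  s_scale <- NULL
  for (f in factors) {
    fl <- downsample_volume(fixed, f)
    ml <- downsample_volume(moving, f)
    rs <- roi_sample(fl, roi, nbins, config$rng_seed, config$max_samples)
    base <- transform_points_matrix(init, rs$pts)
    mb <- array(bin_values(as.numeric(ml$voxels), nbins), ml$geometry$dim)
    w2v <- w2v_matrix(ml$geometry)

    nmi_at <- function(p) {
      cpp_nmi_pv(base, rs$bins, p, cdim, ffd$lattice_origin,
                 ffd$control_spacing, as.integer(mb), ml$geometry$dim, w2v,
                 nbins, 1L)
    }
    r0 <- nmi_at(par)
    if (is.na(r0$cost))
      stop("no image overlap inside the ROI at registration start",
           call. = FALSE)
    nmi_scale <- abs(r0$cost)

    for (outer in seq_len(config$outer_iterations)) {
      corr <- NULL
      if (has_guidance) {
        cur <- compose_transforms(
          bspline_transform(dom, config$control_spacing_mm,
                            array(par, c(cdim, 3))), init)
        corr <- if (inherits(guidance, "correspondence_set")) guidance
        else build_correspondences(guidance$fixed_mask, guidance$moving_mask,
                                   guidance$fixed_lms, guidance$moving_lms,
                                   n_surface_points = config$n_surface_points,
                                   transform = cur,
                                   seed = config$rng_seed + outer)
      }
      if (!is.null(corr)) {
        base_s <- transform_points_matrix(init, corr$p_fixed)
        bm <- basis_matrix(ffd, base_s)
        B <- bm$M
        base_s <- base_s[bm$keep, , drop = FALSE]
        targ <- corr$p_moving[bm$keep, , drop = FALSE]
        src <- corr$source[bm$keep]
        Nm <- corr$normals[bm$keep, , drop = FALSE]
        has_n <- is.finite(Nm[, 1])
        Nm[!has_n, ] <- 0
        npair <- nrow(base_s)
        if (npair == 0) stop("all guidance points left the transform domain",
                             call. = FALSE)
        # squared residual per pair: normal component only where a surface
        # normal is available (point-to-plane), full 3-D distance otherwise
        pair_resid <- function(res) {
          resn <- rowSums(res * Nm)
          list(d2 = ifelse(has_n, resn^2, rowSums(res^2)),
               eff = res * (!has_n) + Nm * resn)
        }
        # each guidance group (surface cloud; landmark centers) is averaged
        # within itself and normalized by its own magnitude at the initial
        # (rigid-baseline) transform, once, then the groups are summed:
        # adding landmark guidance never weakens the surface pull, and the
        # 10/90 weights compare relative improvements. Re-normalizing
        # during optimization would amplify the gradient of an
        # already-converged term.
        wts <- ifelse(src == "surface", 1 / max(sum(src == "surface"), 1),
                      1 / max(sum(src != "surface"), 1))
        if (is.null(s_scale)) {
          P0 <- matrix(par, ncp, 3)
          d0 <- pair_resid(base_s + as.matrix(B %*% P0) - targ)$d2
          s_scale <- vapply(c(surface = "surface", landmark = "landmark"),
                            function(gr) {
                              sel <- (src == "surface") == (gr == "surface")
                              if (!any(sel)) return(1)
                              max(sum(wts[sel] * d0[sel]), 1)
                            }, numeric(1))
        }
        wts <- wts / ifelse(src == "surface", s_scale[["surface"]],
                            s_scale[["landmark"]])
      }
      cache <- new.env()
      evaluate <- function(p) {
        key <- paste0("k", digest_par(p))
        if (!is.null(cache$key) && identical(cache$key, key))
          return(cache$val)
        r <- nmi_at(p)
        if (is.na(r$cost))   # lost overlap: large finite penalty, flat grad
          return(list(value = 100, grad = numeric(ncp * 3)))
        val <- wI * r$cost / nmi_scale
        grad <- wI * as.numeric(r$grad) / nmi_scale
        if (!is.null(corr) && wS > 0) {
          P <- matrix(p, ncp, 3)
          pr <- pair_resid(base_s + as.matrix(B %*% P) - targ)
          val <- val + wS * sum(wts * pr$d2)
          gs <- as.matrix(Matrix::crossprod(B, pr$eff * wts)) * 2
          grad <- grad + wS * as.numeric(gs)
        }
        if (config$bending_energy_weight > 0) {
          bp <- bending_penalty(matrix(p, ncp, 3), cdim)
          val <- val + config$bending_energy_weight * bp$value
          grad <- grad + config$bending_energy_weight * as.numeric(bp$grad)
        }
        out <- list(value = val, grad = grad)
        cache$key <- key; cache$val <- out
        out
      }
      fn <- function(p) evaluate(p)$value
      gr <- function(p) evaluate(p)$grad
      iters <- max(5L, ceiling(config$max_iters / config$outer_iterations))
      if (config$optimizer == "lbfgs") {
        opt <- optim(par, fn, gr, method = "L-BFGS-B",
                     control = list(maxit = iters,
                                    factr = config$convergence_tol /
                                      .Machine$double.eps))
        if (!is.finite(opt$value))
          stop("deformable registration diverged (non-finite cost)",
               call. = FALSE)
        par <- opt$par
        val <- opt$value
      } else {
        opt <- descend(par, fn, gr, iters, config$convergence_tol)
        par <- opt$par
        val <- opt$value
      }
      # without guidance there is nothing to re-estimate, but the outer
      # loop structure (restarted inner solves) is kept identical so that
      # structure_weight = 0 reproduces plain DIR bit for bit
      trace[[length(trace) + 1]] <- list(factor = f, outer = outer,
                                         cost = val)
    }
  }
  bs <- bspline_transform(dom, config$control_spacing_mm,
                          array(par, c(cdim, 3)))
  total <- compose_transforms(bs, init)
  final <- cpp_nmi_pv(transform_points_matrix(init, rs$pts), rs$bins, par,
                      cdim, ffd$lattice_origin, ffd$control_spacing,
                      as.integer(mb), ml$geometry$dim, w2v, nbins, 0L)
  structure(list(transform = total, bspline = bs, rigid_init = init,
                 dvf = to_displacement_field(total, fixed$geometry),
                 diagnostics = list(trace = trace, final_nmi = final$nmi)),
            class = "sgdir_registration")
}

# tiny stable hash for the memoization key (sum-based; collisions only
# matter within one optimizer step, where parameters differ materially)
digest_par <- function(p) {
  sprintf("%.17g_%.17g_%.17g", sum(p), sum(p * seq_along(p)), sum(abs(p)))
}

#' @export
print.sgdir_registration <- function(x, ...) {
  cat("<sgdir_registration> final NMI ", signif(x$diagnostics$final_nmi, 4),
      "; max |coef| ", signif(max(abs(x$bspline$coef)), 4), " mm\n", sep = "")
  invisible(x)
}
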