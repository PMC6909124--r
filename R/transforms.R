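## ---- rigid transforms ----------------------------------------------------

euler_zyx_to_matrix <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

matrix_to_euler_zyx <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  y <- asin(sy)
  if (abs(cos(y)) > 1e-9) {
    z <- atan2(R[2, 1], R[1, 1])
    x <- atan2(R[3, 2], R[3, 3])
  } else {  # gimbal lock
    z <- atan2(-R[1, 2], R[2, 2])
    x <- 0
  }
  c(z, y, x)
}

#' Six-degree-of-freedom rigid transform
#'
#' Parameterized as three Euler angles (radians, applied in Z, then Y, then
#' X order) about a stated rotation center, plus a translation:
#' `T(x) = R (x - center) + center + translation`.
#'
#' @param translation 3-vector mm.
#' @param rotation 3 Euler angles (rad), ZYX order.
#' @param center rotation center, mm.
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(translation = as.numeric(translation),
                 rotation = as.numeric(rotation),
                 center = as.numeric(center),
                 matrix = euler_zyx_to_matrix(as.numeric(rotation))),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> t = (", paste(signif(x$translation, 4), collapse = ", "),
      ") mm; angles = (", paste(signif(x$rotation, 4), collapse = ", "),
      ") rad\n", sep = "")
  invisible(x)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform].
#' @return The inverse `rigid_transform` (same rotation center).
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$matrix)
  out <- rigid_transform(-as.numeric(Rt %*% transform$translation),
                         matrix_to_euler_zyx(Rt), transform$center)
  out$matrix <- Rt
  out
}

## ---- B-spline free-form transforms ---------------------------------------

#' Cubic B-spline free-form deformation
#'
#' `T(x) = x + u(x)` where `u` is a tensor-product cubic B-spline over an
#' axis-aligned lattice of 3-vector coefficients (mm). Zero coefficients
#' give the identity. The transform is defined (and may be evaluated) only
#' on the stated physical domain, inside which every point has a full
#' 4x4x4 coefficient support.
#'
#' @param domain 2 x 3 matrix: rows are the lower and upper corners (mm) of
#'   the physical box the transform must cover.
#' @param control_spacing 3-vector mm: knot spacing of the lattice.
#' @param coefficients optional 4-D array (lattice dim x 3) of coefficient
#'   displacements (mm); default all zero (identity).
#' @return A `bspline_transform` with fields `coef`, `lattice_dim`,
#'   `lattice_origin`, `control_spacing`, `domain`.
#' @export
bspline_transform <- function(domain, control_spacing, coefficients = NULL) {
  domain <- rbind(domain)
  control_spacing <- rep_len(as.numeric(control_spacing), 3)
  lo <- domain[1, ]; hi <- domain[2, ]
  if (any(hi <= lo)) stop("domain upper corner must exceed lower", call. = FALSE)
  n <- as.integer(ceiling((hi - lo) / control_spacing + 1e-9)) + 3L
  corig <- lo - control_spacing
  if (is.null(coefficients)) coefficients <- array(0, c(n, 3L))
  if (!identical(as.integer(dim(coefficients)), c(n, 3L)))
    stop("coefficient array must have dimensions ",
         paste(c(n, 3L), collapse = "x"), call. = FALSE)
  structure(list(coef = coefficients, lattice_dim = n, lattice_origin = corig,
                 control_spacing = control_spacing, domain = domain,
                 order = 3L),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat("<bspline_transform> lattice ", paste(x$lattice_dim, collapse = "x"),
      " @ ", paste(signif(x$control_spacing, 4), collapse = "x"),
      " mm; max |coef| ", signif(max(abs(x$coef)), 4), " mm\n", sep = "")
  invisible(x)
}

# displacement (and optional spatial Jacobian of u) at world points
bspline_displacement <- function(transform, pts, jacobian = FALSE,
                                 strict = TRUE) {
  r <- cpp_bspline_eval(as.numeric(transform$coef), transform$lattice_dim,
                        transform$lattice_origin, transform$control_spacing,
                        rbind(pts), as.integer(jacobian))
  if (strict && !all(r$inside))
    stop(sum(!r$inside), " point(s) outside the B-spline transform domain",
         call. = FALSE)
  r
}

## ---- generic application -------------------------------------------------

# map an n x 3 matrix of world points through any supported transform
transform_points_matrix <- function(transform, pts) {
  pts <- rbind(pts)
  if (inherits(transform, "rigid_transform")) {
    ctr <- transform$center
    sweep(sweep(pts, 2, ctr, "-") %*% t(transform$matrix), 2,
          ctr + transform$translation, "+")
  } else if (inherits(transform, "bspline_transform")) {
    pts + bspline_displacement(transform, pts)$disp
  } else if (inherits(transform, "displacement_field")) {
    w2v <- w2v_matrix(transform$grid)
    disp <- vapply(1:3, function(a) {
      cpp_sample_volume(as.numeric(transform$vectors[, , , a]),
                        transform$grid$dim, w2v, pts, 0L, 0)$values
    }, numeric(nrow(pts)))
    pts + rbind(disp)
  } else if (inherits(transform, "composite_transform")) {
    for (tr in transform$stages) pts <- transform_points_matrix(tr, pts)
    pts
  } else if (is.function(transform)) {
    rbind(transform(pts))
  } else {
    stop("unsupported transform class: ", paste(class(transform), collapse = "/"),
         call. = FALSE)
  }
}

#' Apply a transform to landmarks
#'
#' Maps every point of a landmark set through the transform; names are
#' preserved. Points outside a B-spline transform's domain raise an error.
#'
#' @param transform a [rigid_transform], [bspline_transform],
#'   [displacement_field], composite transform, or a plain function mapping
#'   an n x 3 matrix to an n x 3 matrix.
#' @param points a [landmark_set] (or an n x 3 matrix).
#' @return Object of the same kind as `points`, mapped.
#' @export
apply_to_points <- function(transform, points) {
  if (inherits(points, "landmark_set")) {
    m <- transform_points_matrix(transform, landmark_matrix(points))
    out <- points
    out$points[, c("x", "y", "z")] <- m
    out
  } else {
    transform_points_matrix(transform, points)
  }
}

#' Resample a moving image through a transform
#'
#' Computes `output(x) = moving(T(x))` on the reference grid (pull-back
#' resampling). Out-of-support voxels receive the background value, by
#' default the minimum of the moving image so that air stays air-like.
#'
#' @param transform any transform accepted by [apply_to_points].
#' @param moving an [image_volume] to be resampled.
#' @param reference an [image_volume] or `grid_geometry` defining the
#'   output grid.
#' @param interpolation `"linear"` or `"nearest"` (use nearest for masks).
#' @param background out-of-support fill value.
#' @return An [image_volume] on the reference grid.
#' @export
apply_to_volume <- function(transform, moving, reference,
                            interpolation = c("linear", "nearest"),
                            background = NULL) {
  interpolation <- match.arg(interpolation)
  ref <- geometry_of(reference)
  if (is.null(background)) background <- min(moving$voxels)
  pts <- transform_points_matrix(transform, grid_points(ref))
  s <- cpp_sample_volume(as.numeric(moving$voxels), moving$geometry$dim,
                         w2v_matrix(moving$geometry), pts,
                         as.integer(interpolation == "nearest"), background)
  image_volume(array(s$values, ref$dim), ref$spacing, ref$origin,
               ref$orientation)
}

#' Warp a structure mask through a transform
#'
#' Nearest-neighbour pull-back resampling of the label array, preserving
#' integer labels.
#'
#' @inheritParams apply_to_volume
#' @param mask a [structure_mask] in the moving frame.
#' @return A [structure_mask] on the reference grid.
#' @export
apply_to_mask <- function(transform, mask, reference) {
  vol <- image_volume(mask$labels + 0, mask$geometry$spacing,
                      mask$geometry$origin, mask$geometry$orientation)
  out <- apply_to_volume(transform, vol, reference, "nearest", background = 0)
  structure_mask(out$voxels, out$geometry, mask$label_names)
}

#' Sample a transform into a displacement field
#'
#' `vector(x) = T(x) - x` at every voxel center of the grid, physical mm.
#'
#' @inheritParams apply_to_volume
#' @param grid an [image_volume] or `grid_geometry`.
#' @return A [displacement_field] on `grid`.
#' @export
to_displacement_field <- function(transform, grid) {
  g <- geometry_of(grid)
  pts <- grid_points(g)
  disp <- transform_points_matrix(transform, pts) - pts
  displacement_field(array(disp, c(g$dim, 3L)), g)
}

## ---- composition ---------------------------------------------------------

#' Compose two transforms
#'
#' Returns the transform `x -> outer(inner(x))`. Two rigid transforms
#' compose in closed form to a rigid transform; any other combination is
#' returned as a composite that applies `inner` first. A composite can be
#' sampled onto a grid with [to_displacement_field()].
#'
#' @param outer,inner transforms accepted by [apply_to_points].
#' @return A [rigid_transform] or a `composite_transform`.
#' @export
compose_transforms <- function(outer, inner) {
  if (inherits(outer, "rigid_transform") && inherits(inner, "rigid_transform")) {
    Rm <- outer$matrix %*% inner$matrix
    ci <- inner$center
    t_new <- as.numeric(outer$matrix %*% (ci + inner$translation - outer$center)) +
      outer$center + outer$translation - ci
    out <- rigid_transform(t_new, matrix_to_euler_zyx(Rm), ci)
    out$matrix <- Rm
    return(out)
  }
  stages <- c(if (inherits(inner, "composite_transform")) inner$stages else list(inner),
              if (inherits(outer, "composite_transform")) outer$stages else list(outer))
  structure(list(stages = stages), class = "composite_transform")
}

#' @export
print.composite_transform <- function(x, ...) {
  cat("<composite_transform> ", length(x$stages), " stages\n", sep = "")
  invisible(x)
}
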