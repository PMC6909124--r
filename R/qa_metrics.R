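## ---- Dice ----------------------------------------------------------------

#' Dice similarity coefficient
#'
#' Volumetric overlap `2 |A n B| / (|A| + |B|)` between two labelled
#' structures, computed on voxel counts. If the masks live on different
#' grids, `b` is resampled onto `a`'s grid with nearest-neighbour
#' interpolation first.
#'
#' @param a,b [structure_mask]s.
#' @param label_a,label_b label value or name selecting the structure in
#'   each mask.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b, label_a = a$label_names[[1]], label_b = b$label_names[[1]]) {
  A <- mask_indicator(a, label_a)
  if (!same_geometry(a$geometry, b$geometry)) {
    b <- apply_to_mask(rigid_transform(), b, a$geometry)
  }
  B <- mask_indicator(b, label_b)
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0)
    stop("DSC undefined: both structures are empty", call. = FALSE)
  2 * sum(A & B) / (na + nb)
}

## ---- surface extraction and MDA ------------------------------------------

# logical array: masked voxels with at least one 6-connected background
# neighbour (voxels on the array border count as boundary)
surface_voxels <- function(ind) {
  d <- dim(ind)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- ind
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  core & !nb
}

#' Physical coordinates of a structure's surface voxels
#'
#' The surface is the set of masked voxels having at least one six-connected
#' background neighbour; coordinates are voxel centers in mm.
#'
#' @param mask a [structure_mask].
#' @param label label value or name.
#' @return n x 3 matrix of mm coordinates.
#' @export
surface_points <- function(mask, label = mask$label_names[[1]]) {
  ind <- mask_indicator(mask, label)
  if (!any(ind)) stop("empty structure: no surface", call. = FALSE)
  idx <- which(surface_voxels(ind), arr.ind = TRUE) - 1
  voxel_to_world(mask$geometry, idx)
}

#' Mean distance to agreement (mean surface distance)
#'
#' Directed form: the minimum distance from each surface point of structure
#' `b` to the surface of structure `a`, averaged over `b`'s surface points.
#' The symmetric option averages the two directed values.
#'
#' @param b,a [structure_mask]s (distances run from `b`'s surface to `a`'s).
#' @param label_b,label_a label value or name in each mask.
#' @param symmetric average of the two directed MDAs instead.
#' @return MDA in mm.
#' @export
mean_distance_to_agreement <- function(b, a,
                                       label_b = b$label_names[[1]],
                                       label_a = a$label_names[[1]],
                                       symmetric = FALSE) {
  sb <- surface_points(b, label_b)
  sa <- surface_points(a, label_a)
  d_ba <- mean(cpp_min_dists(sb, sa))
  if (!symmetric) return(d_ba)
  (d_ba + mean(cpp_min_dists(sa, sb))) / 2
}

## ---- TRE -----------------------------------------------------------------

#' Target registration error per landmark
#'
#' Euclidean distance, in mm, between name-paired landmarks after
#' registration: `TRE = sqrt(dx^2 + dy^2 + dz^2)` per pair, with cohort
#' summaries (median, range, mean, SEM).
#'
#' @param mapped_lms fixed-image landmarks mapped through the registration
#'   (a [landmark_set] in the moving frame).
#' @param reference_lms the moving-image landmarks they should coincide
#'   with.
#' @return A `tre_result`: data.frame `pairs` (name, dx, dy, dz, tre_mm)
#'   plus `median`, `range`, `mean`, `sem`, `n`.
#' @export
target_registration_error <- function(mapped_lms, reference_lms) {
  pr <- pair_landmarks(mapped_lms, reference_lms)
  d <- pr$a - pr$b
  tre <- sqrt(rowSums(d^2))
  pairs <- data.frame(name = pr$names, dx = d[, 1], dy = d[, 2], dz = d[, 3],
                      tre_mm = tre, stringsAsFactors = FALSE)
  structure(list(pairs = pairs, median = median(tre), range = range(tre),
                 mean = mean(tre),
                 sem = if (length(tre) > 1) sd(tre) / sqrt(length(tre)) else 0,
                 n = length(tre)),
            class = "tre_result")
}

#' @export
print.tre_result <- function(x, ...) {
  cat("<tre_result> n = ", x$n, "; median ", signif(x$median, 3),
      " mm (", signif(x$range[1], 3), "-", signif(x$range[2], 3),
      "); mean ", signif(x$mean, 3), " +/- ", signif(x$sem, 2), " mm\n",
      sep = "")
  invisible(x)
}

## ---- Jacobian map --------------------------------------------------------

#' Jacobian-determinant map of a displacement field
#'
#' Per-voxel `J = det(I + du/dx)` with displacement gradients taken by
#' central differences in physical mm (one-sided at array boundaries, which
#' are flagged invalid). `J = 1` means no volume change, `J < 1` local
#' contraction, `J > 1` expansion, and `J < 0` folding (non-physical
#' motion).
#'
#' @param field a [displacement_field] with at least 3 voxels per axis.
#' @return A `jacobian_map`: list with `values` (3-D array), `grid`,
#'   `validity`.
#' @export
jacobian_map <- function(field) {
  g <- field$grid
  if (any(g$dim < 3L))
    stop("Jacobian needs at least 3 voxels per axis", call. = FALSE)
  # d(index)/d(world): inverse of orientation %*% diag(spacing)
  Ainv <- diag(1 / g$spacing) %*% t(g$orientation)
  d <- g$dim
  # index-space gradients of each displacement component
  gidx <- function(arr, axis) {
    n <- d[axis]
    fwd <- function(k) pmin(k + 1L, n)
    bwd <- function(k) pmax(k - 1L, 1L)
    k <- seq_len(n)
    if (axis == 1L) {
      num <- arr[fwd(k), , , drop = FALSE] - arr[bwd(k), , , drop = FALSE]
    } else if (axis == 2L) {
      num <- arr[, fwd(k), , drop = FALSE] - arr[, bwd(k), , drop = FALSE]
    } else {
      num <- arr[, , fwd(k), drop = FALSE] - arr[, , bwd(k), drop = FALSE]
    }
    den <- rep(2, n); den[1] <- 1; den[n] <- 1
    sweep(num, axis, den, "/")
  }
  G <- array(0, c(d, 3, 3))  # G[..., a, b] = d u_a / d world_b
  for (a in 1:3) {
    ua <- field$vectors[, , , a]
    for (ia in 1:3) {
      gi <- gidx(ua, ia)
      for (b in 1:3) {
        if (Ainv[ia, b] != 0)
          G[, , , a, b] <- G[, , , a, b] + gi * Ainv[ia, b]
      }
    }
  }
  J <- (1 + G[, , , 1, 1]) * ((1 + G[, , , 2, 2]) * (1 + G[, , , 3, 3]) -
                                G[, , , 2, 3] * G[, , , 3, 2]) -
    G[, , , 1, 2] * (G[, , , 2, 1] * (1 + G[, , , 3, 3]) -
                       G[, , , 2, 3] * G[, , , 3, 1]) +
    G[, , , 1, 3] * (G[, , , 2, 1] * G[, , , 3, 2] -
                       (1 + G[, , , 2, 2]) * G[, , , 3, 1])
  interior <- array(TRUE, d)
  interior[c(1, d[1]), , ] <- FALSE
  interior[, c(1, d[2]), ] <- FALSE
  interior[, , c(1, d[3])] <- FALSE
  structure(list(values = J, grid = g,
                 validity = interior & field$validity),
            class = "jacobian_map")
}

#' @export
print.jacobian_map <- function(x, ...) {
  v <- x$values[x$validity]
  cat("<jacobian_map> ", format(x$grid), "; J in [",
      signif(min(v), 4), ", ", signif(max(v), 4), "]\n", sep = "")
  invisible(x)
}

#' Percentage of a structure with negative Jacobian determinant
#'
#' Fraction (as a percentage) of the structure's valid voxels where the
#' deformation folds (`J < 0`).
#'
#' @param jmap a [jacobian_map].
#' @param mask a [structure_mask] on the same grid.
#' @param label label value or name.
#' @return percentage in `[0, 100]`.
#' @export
negative_jacobian_fraction <- function(jmap, mask,
                                       label = mask$label_names[[1]]) {
  if (!same_geometry(jmap$grid, mask$geometry))
    stop("Jacobian map and mask must share a grid", call. = FALSE)
  sel <- mask_indicator(mask, label) & jmap$validity
  if (!any(sel)) stop("no valid voxels inside the structure", call. = FALSE)
  100 * sum(jmap$values[sel] < 0) / sum(sel)
}

## ---- cumulative displacement histogram -----------------------------------

#' Masked cumulative displacement histogram
#'
#' For thresholds `t_k = k * bin_width`, the fraction of the structure's
#' valid voxels whose displacement magnitude is at most `t_k`. The curve is
#' monotone non-decreasing and ends at 1. Mean and SEM of the magnitude are
#' also reported.
#'
#' @param field a [displacement_field] on the mask's grid (resample with
#'   [resample_to_grid()] first if needed).
#' @param mask a [structure_mask].
#' @param label label value or name.
#' @param bin_width_mm histogram bin width, mm.
#' @return A `cum_hist`: data.frame `curve` (threshold_mm,
#'   cumulative_fraction) plus `mean`, `sem`, `n`.
#' @export
cumulative_displacement_histogram <- function(field, mask,
                                              label = mask$label_names[[1]],
                                              bin_width_mm = 0.1) {
  if (!same_geometry(field$grid, mask$geometry))
    stop("field and mask must share a grid; resample the field first",
         call. = FALSE)
  sel <- mask_indicator(mask, label) & field$validity
  if (!any(sel)) stop("no valid voxels inside the structure", call. = FALSE)
  mag <- field_magnitude(field)[sel]
  kmax <- max(1, ceiling(max(mag) / bin_width_mm - 1e-9))
  thr <- (0:kmax) * bin_width_mm
  frac <- vapply(thr, function(t) mean(mag <= t + 1e-9), numeric(1))
  structure(list(curve = data.frame(threshold_mm = thr,
                                    cumulative_fraction = frac),
                 mean = mean(mag),
                 sem = if (length(mag) > 1) sd(mag) / sqrt(length(mag)) else 0,
                 n = length(mag)),
            class = "cum_hist")
}

#' @export
print.cum_hist <- function(x, ...) {
  cat("<cum_hist> n = ", x$n, "; mean |u| ", signif(x$mean, 4), " mm (SEM ",
      signif(x$sem, 3), ")\n", sep = "")
  invisible(x)
}

## ---- per-case QA report --------------------------------------------------

#' Full registration QA report for one case
#'
#' Bundles the TG-132 metrics for a single registration: warps the moving
#' structure onto the fixed grid, computes DSC and MDA against the fixed
#' structure, maps the fixed landmarks and computes TRE against the moving
#' landmarks, samples the transform into a displacement field on the fixed
#' grid, and derives Jacobian statistics and the masked cumulative
#' displacement histogram.
#'
#' @param transform the registration result (any transform accepted by
#'   [apply_to_points], including a [displacement_field]).
#' @param fixed_mask [structure_mask] on the fixed (planning) grid.
#' @param moving_mask [structure_mask] in the moving frame.
#' @param fixed_lms,moving_lms paired [landmark_set]s (optional; TRE is
#'   omitted when absent).
#' @param label structure of interest (value or name).
#' @param bin_width_mm histogram bin width.
#' @return A `qa_report` list: `dsc`, `mda_mm`, `tre` ([target_registration_error]
#'   result or NULL), `jacobian` (list `min`, `pct_negative`),
#'   `cum_hist`, `dvf`.
#' @export
qa_report <- function(transform, fixed_mask, moving_mask,
                      fixed_lms = NULL, moving_lms = NULL,
                      label = fixed_mask$label_names[[1]],
                      bin_width_mm = 0.1) {
  warped <- apply_to_mask(transform, moving_mask, fixed_mask$geometry)
  dsc <- dice(fixed_mask, warped, label_a = label, label_b = label)
  mda <- mean_distance_to_agreement(warped, fixed_mask,
                                    label_b = label, label_a = label)
  tre <- NULL
  if (!is.null(fixed_lms) && !is.null(moving_lms)) {
    mapped <- apply_to_points(transform, fixed_lms)
    tre <- target_registration_error(mapped, moving_lms)
  }
  dvf <- if (inherits(transform, "displacement_field") &&
             same_geometry(transform$grid, fixed_mask$geometry)) {
    transform
  } else {
    to_displacement_field(transform, fixed_mask$geometry)
  }
  jmap <- jacobian_map(dvf)
  jac <- list(min = min(jmap$values[jmap$validity]),
              pct_negative = negative_jacobian_fraction(jmap, fixed_mask,
                                                        label = label))
  ch <- cumulative_displacement_histogram(dvf, fixed_mask, label = label,
                                          bin_width_mm = bin_width_mm)
  structure(list(dsc = dsc, mda_mm = mda, tre = tre, jacobian = jac,
                 cum_hist = ch, dvf = dvf),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report> DSC ", signif(x$dsc, 3), "; MDA ", signif(x$mda_mm, 3),
      " mm; ", if (!is.null(x$tre)) paste0("TRE median ",
                                           signif(x$tre$median, 3), " mm; "),
      "%J<0 ", signif(x$jacobian$pct_negative, 3), "\n", sep = "")
  invisible(x)
}
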