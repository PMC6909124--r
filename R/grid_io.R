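#' @useDynLib sgdir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optim quantile rnorm runif sd setNames
NULL

## ---- grid geometry -------------------------------------------------------

#' Physical grid geometry
#'
#' Describes the sampling grid of a volume: array dimensions, voxel spacing
#' (mm), physical origin of voxel (0,0,0) (mm), and a 3x3 direction-cosine
#' matrix. The physical position of 0-based voxel index `i` is
#' `origin + orientation %*% (spacing * i)`. All physical coordinates in this
#' package are millimetres in the image's stated anatomical frame
#' (nominally LPS).
#'
#' @param dim integer 3-vector of array dimensions.
#' @param spacing numeric 3-vector, mm per voxel, all > 0.
#' @param origin numeric 3-vector, mm.
#' @param orientation 3x3 orthonormal direction matrix (|det| = 1).
#' @return A `grid_geometry` object.
#' @export
grid_geometry <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          orientation = diag(3)) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- matrix(as.numeric(orientation), 3, 3)
  if (length(dim) != 3L || any(dim < 1L))
    stop("grid dimensions must be a positive integer 3-vector", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("degenerate spacing: all components must be finite and > 0", call. = FALSE)
  if (abs(abs(det(orientation)) - 1) > 1e-6 ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation matrix must be orthonormal", call. = FALSE)
  structure(list(dim = dim, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "grid_geometry")
}

#' @export
format.grid_geometry <- function(x, ...) {
  sprintf("grid %s @ %s mm", paste(x$dim, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"))
}

#' @export
print.grid_geometry <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$orientation - b$orientation)) < tol
}

#' Voxel index to physical coordinate mapping
#'
#' @param geom a `grid_geometry`.
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of physical mm coordinates.
#' @export
voxel_to_world <- function(geom, idx) {
  idx <- rbind(idx)
  sweep(idx %*% diag(geom$spacing) %*% t(geom$orientation), 2, geom$origin, "+")
}

#' @rdname voxel_to_world
#' @param pts n x 3 matrix of physical mm coordinates.
#' @export
world_to_voxel <- function(geom, pts) {
  pts <- rbind(pts)
  sweep(pts, 2, geom$origin, "-") %*% geom$orientation %*% diag(1 / geom$spacing)
}

# 3x4 world-to-voxel affine used by the C++ samplers
w2v_matrix <- function(geom) {
  A <- diag(1 / geom$spacing) %*% t(geom$orientation)
  cbind(A, -A %*% geom$origin)
}

# physical coordinates of every voxel center, in array (column-major) order
grid_points <- function(geom) {
  d <- geom$dim
  idx <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(geom, idx)
}

## ---- image volume --------------------------------------------------------

#' 3-D scalar image volume with physical geometry
#'
#' @param voxels 3-D numeric array of intensities (arbitrary units).
#' @inheritParams grid_geometry
#' @return An `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = diag(3)) {
  if (length(dim(voxels)) != 3L)
    stop("image volume must be a 3-D array", call. = FALSE)
  geom <- grid_geometry(dim(voxels), spacing, origin, orientation)
  structure(list(voxels = voxels, geometry = geom), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", format(x$geometry), "\n", sep = "")
  invisible(x)
}

geometry_of <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  if (!is.null(x$geometry)) return(x$geometry)
  if (!is.null(x$grid)) return(x$grid)
  stop("object carries no grid geometry", call. = FALSE)
}

## ---- structure mask ------------------------------------------------------

#' Integer label mask on an image grid
#'
#' Label 0 is background. `label_names` maps label values to names, e.g.
#' `c(liver = 1, portal_vein = 2)`.
#'
#' @param labels 3-D integer array.
#' @param geometry a `grid_geometry` (or an object carrying one).
#' @param label_names named integer vector mapping name to label value.
#' @return A `structure_mask`.
#' @export
structure_mask <- function(labels, geometry, label_names = c(structure = 1L)) {
  geometry <- geometry_of(geometry)
  if (!identical(dim(labels), dim(array(0L, geometry$dim))) &&
      !identical(as.integer(dim(labels)), geometry$dim))
    stop("mask array dimensions must match the grid", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, geometry = geometry,
                 label_names = label_names),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat("<structure_mask> ", format(x$geometry), "; labels: ",
      paste(names(x$label_names), collapse = ", "), "\n", sep = "")
  invisible(x)
}

resolve_label <- function(mask, label) {
  if (is.character(label)) {
    if (!label %in% names(mask$label_names))
      stop("unknown label name: ", label, call. = FALSE)
    label <- mask$label_names[[label]]
  }
  as.integer(label)
}

#' Physical volume of a labelled structure
#'
#' Voxel count times voxel volume (product of the grid spacing).
#'
#' @param mask a `structure_mask`.
#' @param label label value or name (default: first named label).
#' @return volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask, label = mask$label_names[[1]]) {
  lab <- resolve_label(mask, label)
  if (!lab %in% mask$label_names && !any(mask$labels == lab))
    stop("unknown label: ", label, call. = FALSE)
  sum(mask$labels == lab) * prod(mask$geometry$spacing)
}

# logical array for one label
mask_indicator <- function(mask, label = mask$label_names[[1]]) {
  mask$labels == resolve_label(mask, label)
}

## ---- landmark set --------------------------------------------------------

#' Named landmark points in physical mm
#'
#' A study-quality set carries 6 to 11 points (a warning, not an error, is
#' raised outside that range when `check = TRUE`).
#'
#' @param points data.frame with columns name, x, y, z (mm).
#' @param frame identifier of the image frame the points live in.
#' @param check warn when the number of points is outside 6..11.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(points, frame = "unknown", check = FALSE) {
  points <- as.data.frame(points)
  if (!all(c("name", "x", "y", "z") %in% names(points)))
    stop("landmark points need columns name, x, y, z", call. = FALSE)
  points$name <- as.character(points$name)
  for (cl in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(points[[cl]]))
    if (any(is.na(v)))
      stop("non-numeric landmark coordinate in column ", cl, call. = FALSE)
    points[[cl]] <- v
  }
  if (anyDuplicated(points$name))
    stop("duplicate landmark names: ",
         paste(unique(points$name[duplicated(points$name)]), collapse = ", "),
         call. = FALSE)
  if (check && (nrow(points) < 6 || nrow(points) > 11))
    warning("landmark set has ", nrow(points),
            " points; typical study sets carry 6-11", call. = FALSE)
  structure(list(points = points[, c("name", "x", "y", "z")], frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", nrow(x$points), " points in frame '", x$frame, "'\n",
      sep = "")
  invisible(x)
}

landmark_matrix <- function(lms) {
  as.matrix(lms$points[, c("x", "y", "z")])
}

#' Pair two landmark sets by name
#'
#' @param a,b `landmark_set`s with equal name sets.
#' @return list with `names` and aligned coordinate matrices `a`, `b`.
#' @export
pair_landmarks <- function(a, b) {
  if (!setequal(a$points$name, b$points$name))
    stop("landmark sets are not paired: name sets differ", call. = FALSE)
  ord <- match(a$points$name, b$points$name)
  list(names = a$points$name,
       a = landmark_matrix(a),
       b = landmark_matrix(b)[ord, , drop = FALSE])
}

## ---- displacement field --------------------------------------------------

#' Per-voxel displacement field (mm)
#'
#' Vectors live on the stated grid under the fixed-grid pull-back
#' convention: the vector stored at a fixed-image voxel points from that
#' voxel's physical position to the corresponding physical location in the
#' moving image. An identity field is all zeros.
#'
#' @param vectors 4-D array `dim(grid) x 3` of mm displacement components.
#' @param grid a `grid_geometry` (or an object carrying one).
#' @param validity optional logical array marking voxels whose vectors are
#'   trustworthy (e.g. in-support after resampling); default all `TRUE`.
#' @return A `displacement_field`.
#' @export
displacement_field <- function(vectors, grid, validity = NULL) {
  grid <- geometry_of(grid)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L || !identical(as.integer(d[1:3]), grid$dim))
    stop("vector array must have shape grid dim x 3", call. = FALSE)
  if (is.null(validity)) validity <- array(TRUE, grid$dim)
  structure(list(vectors = vectors, grid = grid, validity = validity,
                 convention = "fixed-grid pull-back"),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat("<displacement_field> ", format(x$grid), "; |u| max ",
      signif(max(mag), 4), " mm\n", sep = "")
  invisible(x)
}

# displacement magnitude array
field_magnitude <- function(field) {
  sqrt(field$vectors[, , , 1]^2 + field$vectors[, , , 2]^2 +
         field$vectors[, , , 3]^2)
}

## ---- NIfTI I/O -----------------------------------------------------------

geom_to_xform <- function(geom) {
  m <- diag(4)
  m[1:3, 1:3] <- geom$orientation %*% diag(geom$spacing)
  m[1:3, 4] <- geom$origin
  m
}

xform_to_geom <- function(m, dim) {
  A <- m[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("degenerate spacing in NIfTI header", call. = FALSE)
  grid_geometry(dim, spacing, m[1:3, 4], A %*% diag(1 / spacing))
}

write_nifti_array <- function(arr, geom, path) {
  im <- RNifti::asNifti(arr)
  RNifti::`sform<-`(im, structure(geom_to_xform(geom), code = 2L)) -> im
  RNifti::writeNifti(im, path)
  invisible(path)
}

read_nifti_array <- function(path, ndim_expected = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  im <- tryCatch(RNifti::readNifti(path),
                 error = function(e) stop("not a readable NIfTI file: ", path,
                                          call. = FALSE))
  arr <- as.array(im)
  # drop trailing singleton dims (NIfTI pads dims with 1) and strip the
  # reader's attributes so plain arrays come out
  d <- dim(arr)
  while (length(d) > 3 && d[length(d)] == 1L) d <- d[-length(d)]
  arr <- array(as.numeric(arr), dim = d)
  m <- RNifti::xform(im, useQuaternionFirst = FALSE)
  list(arr = arr, xform = unclass(m)[1:4, 1:4])
}

#' Read / write a scalar volume as NIfTI
#'
#' Geometry is taken from (written to) the sform affine. Intensities are as
#' stored, after the header slope/intercept scaling applied by the reader.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @return An [image_volume].
#' @export
read_volume <- function(path) {
  r <- read_nifti_array(path)
  if (length(dim(r$arr)) != 3L)
    stop("expected a 3-D scalar image, got ", length(dim(r$arr)),
         " dimensions: ", path, call. = FALSE)
  geom <- xform_to_geom(r$xform, dim(r$arr))
  image_volume(r$arr, geom$spacing, geom$origin, geom$orientation)
}

#' @rdname read_volume
#' @param volume an [image_volume].
#' @export
write_volume <- function(volume, path) {
  write_nifti_array(volume$voxels, volume$geometry, path)
}

#' Read / write a structure mask as integer NIfTI
#'
#' @param path a `.nii` / `.nii.gz` file with integer labels.
#' @param label_names named integer vector mapping names to label values.
#' @return A [structure_mask].
#' @export
read_mask <- function(path, label_names = NULL) {
  vol <- read_volume(path)
  labs <- round(vol$voxels)
  if (max(abs(labs - vol$voxels)) > 1e-6)
    warning("mask voxels were not integer-valued; rounded", call. = FALSE)
  if (is.null(label_names)) {
    vals <- sort(setdiff(unique(as.integer(labs)), 0L))
    label_names <- setNames(vals, paste0("label", vals))
    if (length(vals) == 1L) names(label_names) <- "structure"
  }
  structure_mask(labs, vol$geometry, label_names)
}

#' @rdname read_mask
#' @param mask a [structure_mask].
#' @export
write_mask <- function(mask, path) {
  write_nifti_array(mask$labels, mask$geometry, path)
}

dvf_sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".yaml", path)
}

#' Read / write a displacement vector field as vector NIfTI
#'
#' Fields are stored as 4-D NIfTI (x, y, z, component) with physical-mm
#' components; a YAML sidecar records the displacement convention
#' (fixed-grid pull-back) and is asserted on read when present.
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @return A [displacement_field].
#' @export
read_dvf <- function(path) {
  r <- read_nifti_array(path)
  d <- dim(r$arr)
  if (length(d) == 5L && d[4] == 1L) {       # NIfTI vector convention (t=1)
    dim(r$arr) <- d[c(1:3, 5)]
    d <- dim(r$arr)
  }
  if (length(d) != 4L)
    stop("expected a 4-D vector image: ", path, call. = FALSE)
  if (d[4] != 3L)
    stop("displacement field must have 3 components per voxel, found ",
         d[4], call. = FALSE)
  geom <- xform_to_geom(r$xform, d[1:3])
  side <- dvf_sidecar_path(path)
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (!is.null(meta$convention) &&
        !identical(meta$convention, "fixed-grid pull-back"))
      stop("displacement field declares convention '", meta$convention,
           "'; this toolkit expects 'fixed-grid pull-back'", call. = FALSE)
  }
  displacement_field(r$arr, geom)
}

#' @rdname read_dvf
#' @param field a [displacement_field].
#' @export
write_dvf <- function(field, path) {
  write_nifti_array(field$vectors, field$grid, path)
  yaml::write_yaml(list(convention = field$convention, units = "mm"),
                   dvf_sidecar_path(path))
  invisible(path)
}

#' Read / write landmarks (CSV or JSON)
#'
#' CSV files carry a `name,x,y,z` header with mm coordinates; JSON files an
#' object `{frame: ..., points: [{name, x, y, z}, ...]}`.
#'
#' @param path a `.csv` or `.json` file.
#' @param frame frame identifier attached to the returned set (CSV only;
#'   JSON files carry their own).
#' @return A [landmark_set].
#' @export
read_landmarks <- function(path, frame = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- as.data.frame(obj$points)
    if (!is.null(obj$frame)) frame <- obj$frame
  } else {
    pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  landmark_set(pts, frame = frame)
}

#' @rdname read_landmarks
#' @param lms a [landmark_set].
#' @export
write_landmarks <- function(lms, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(frame = lms$frame, points = lms$points), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(lms$points, path, row.names = FALSE)
  }
  invisible(path)
}

## ---- resampling ----------------------------------------------------------

#' Resample a displacement field onto a reference grid
#'
#' Each vector component is interpolated linearly in physical space at the
#' reference grid's voxel centers. Voxels outside the field's support are
#' assigned zero vectors and flagged `FALSE` in the output's validity mask.
#'
#' @param field a [displacement_field].
#' @param reference an [image_volume] or `grid_geometry` defining the
#'   output grid.
#' @param interpolation only `"linear"` is supported.
#' @return A [displacement_field] on the reference geometry.
#' @export
resample_to_grid <- function(field, reference, interpolation = "linear") {
  interpolation <- match.arg(interpolation, "linear")
  ref <- geometry_of(reference)
  pts <- grid_points(ref)
  w2v <- w2v_matrix(field$grid)
  out <- array(0, c(ref$dim, 3L))
  inside <- NULL
  for (a in 1:3) {
    s <- cpp_sample_volume(as.numeric(field$vectors[, , , a]), field$grid$dim,
                           w2v, pts, 0L, 0)
    out[, , , a] <- array(s$values, ref$dim)
    inside <- if (is.null(inside)) s$inside else inside & s$inside
  }
  if (!any(inside))
    stop("field and reference grid have disjoint physical extents",
         call. = FALSE)
  for (a in 1:3) {
    comp <- out[, , , a]
    comp[!array(inside, ref$dim)] <- 0
    out[, , , a] <- comp
  }
  displacement_field(out, ref, validity = array(inside, ref$dim))
}
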