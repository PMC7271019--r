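# Data model and NIfTI readers/writers for masks and BOLD series.

#' Construct a binary mask volume
#'
#' A `mask_volume` is the spatial domain of an ROI or target: a binary 3D
#' grid plus the voxel-to-world (RAS, mm) affine.
#'
#' @param values 3D array of 0/1 (or logical) voxel values.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices to mm).
#' @return A `mask_volume` object.
#' @export
mask_volume <- function(values, affine = diag(4)) {
  stopifnot(length(dim(values)) == 3L, all(dim(values) > 0L))
  affine <- unclass(as.matrix(affine))[1:4, 1:4]
  if (abs(det(affine)) < 1e-12)
    stop("mask affine is not invertible")
  v <- array(as.integer(values != 0), dim = dim(values))
  if (!all(values %in% c(0, 1, TRUE, FALSE)))
    stop("mask values are not binary")
  structure(list(values = v, affine = affine), class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s grid, %d voxels in mask, %s mm voxels\n",
              paste(dim(x$values), collapse = "x"), sum(x$values),
              paste(signif(voxel_size(x), 3), collapse = "x")))
  invisible(x)
}

#' Voxel edge lengths (mm) of a volume's grid
#' @param x a `mask_volume` or `bold_series`.
#' @return Numeric length-3 vector of voxel sizes in mm.
#' @export
voxel_size <- function(x) {
  sqrt(colSums(x$affine[1:3, 1:3]^2))
}

#' 0-based grid coordinates of in-mask voxels
#'
#' Voxel coordinates are 0-based (i, j, k) grid indices throughout; world
#' (mm) coordinates are obtained through the affine.
#'
#' @param mask a `mask_volume`.
#' @return Integer matrix, one row per in-mask voxel, columns i, j, k.
#'   Rows follow column-major grid order (i fastest), the canonical voxel
#'   ordering used for connectivity rows and label vectors.
#' @export
mask_coordinates <- function(mask) {
  idx <- which(mask$values != 0, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  idx <- idx - 1L
  dimnames(idx) <- list(NULL, c("i", "j", "k"))
  idx
}

#' World (mm) coordinates of 0-based voxel indices
#' @param coords n x 3 matrix of 0-based voxel indices.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(coords, affine) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  t(affine[1:3, 1:3] %*% t(coords) + affine[1:3, 4])
}

.read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  RNifti::readNifti(path)
}

#' Read a binary 3D mask from a NIfTI-1 file
#'
#' The on-disk voxel values must already be binary (0/1): non-binary data is
#' rejected with an error rather than silently thresholded, so an invalid
#' ROI (e.g. a probabilistic map) is reported instead of coerced.
#'
#' @param path path to a 3D `.nii`/`.nii.gz` file.
#' @return A [mask_volume()].
#' @export
read_mask <- function(path) {
  img <- .read_nifti_raw(path)
  if (length(dim(img)) != 3L)
    stop("mask must be a 3D image, got ", length(dim(img)), "D: ", path)
  vals <- as.array(img)
  if (!all(vals %in% c(0, 1)))
    stop("mask is not binary (values outside {0,1} found): ", path)
  mask_volume(vals, affine = .xform_matrix(img))
}

.xform_matrix <- function(img) {
  m <- RNifti::xform(img)
  unclass(as.matrix(m))[1:4, 1:4]
}

.write_nifti_with_affine <- function(values, affine, path, datatype = NULL) {
  im <- RNifti::asNifti(values)
  aff <- structure(affine, code = 2L)
  RNifti::`sform<-`(im, aff) -> im
  RNifti::`qform<-`(im, aff) -> im
  RNifti::pixdim(im) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::writeNifti(im, path, datatype = if (is.null(datatype)) "auto" else datatype)
  invisible(path)
}

#' Write a mask volume to NIfTI-1
#' @param mask a [mask_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  .write_nifti_with_affine(mask$values, mask$affine, path, datatype = "uint8")
}

#' Write an integer label image on an ROI grid to NIfTI-1
#'
#' Maps a per-voxel label vector back onto the ROI mask grid (0 outside the
#' ROI) and stores it as a NIfTI image, the standard way group parcellations
#' are delivered for viewing.
#'
#' @param labels integer labels, one per in-mask ROI voxel, in
#'   [mask_coordinates()] order.
#' @param roi the ROI [mask_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, roi, path) {
  stopifnot(length(labels) == sum(roi$values))
  vol <- array(0L, dim = dim(roi$values))
  vol[roi$values != 0] <- as.integer(labels)
  .write_nifti_with_affine(vol, roi$affine, path, datatype = "int16")
}

#' Read an integer label image over an ROI
#' @param path path to a NIfTI label image.
#' @param roi the ROI [mask_volume()] defining which voxels to extract.
#' @return Integer label vector in [mask_coordinates()] order.
#' @export
read_label_image <- function(path, roi) {
  img <- .read_nifti_raw(path)
  if (!identical(dim(img)[1:3], dim(roi$values)))
    stop("label image grid does not match ROI grid")
  vals <- as.array(img)
  as.integer(vals[roi$values != 0])
}

#' Construct a BOLD time-series volume
#' @param values 4D array (x, y, z, time).
#' @param tr_seconds repetition time in seconds.
#' @param affine 4x4 voxel-to-world matrix.
#' @return A `bold_series` object.
#' @export
bold_series <- function(values, tr_seconds, affine = diag(4)) {
  stopifnot(length(dim(values)) == 4L, dim(values)[4] >= 2L, tr_seconds > 0)
  structure(list(values = values, tr_seconds = as.numeric(tr_seconds),
                 affine = unclass(as.matrix(affine))[1:4, 1:4]),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<bold_series> %s grid, %d timepoints, TR = %gs\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr_seconds))
  invisible(x)
}

#' Read a 4D BOLD series from NIfTI-1
#' @param path path to a 4D NIfTI file.
#' @param tr_seconds repetition time; if `NULL`, taken from the NIfTI
#'   header's fourth pixdim entry.
#' @return A [bold_series()].
#' @export
read_bold <- function(path, tr_seconds = NULL) {
  img <- .read_nifti_raw(path)
  if (length(dim(img)) != 4L)
    stop("BOLD series must be a 4D image: ", path)
  if (is.null(tr_seconds)) {
    pd <- attr(img, "pixdim")
    if (is.null(pd)) pd <- RNifti::pixdim(img)
    tr_seconds <- if (length(pd) >= 4) pd[4] else 1
    if (!is.finite(tr_seconds) || tr_seconds <= 0) tr_seconds <- 1
  }
  bold_series(as.array(img), tr_seconds = tr_seconds,
              affine = .xform_matrix(img))
}

#' Write a BOLD series to NIfTI-1
#' @param series a [bold_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bold <- function(series, path) {
  im <- RNifti::asNifti(series$values)
  aff <- structure(series$affine, code = 2L)
  RNifti::`sform<-`(im, aff) -> im
  RNifti::`qform<-`(im, aff) -> im
  RNifti::pixdim(im) <- c(sqrt(colSums(series$affine[1:3, 1:3]^2)),
                          series$tr_seconds)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Extract in-mask voxel time series as a matrix
#' @param series a [bold_series()].
#' @param mask a [mask_volume()] on the same grid.
#' @return timepoints x voxels matrix, columns in [mask_coordinates()] order.
#' @export
series_matrix <- function(series, mask) {
  d <- dim(series$values)
  if (!identical(d[1:3], dim(mask$values)))
    stop("BOLD grid does not match mask grid")
  flat <- matrix(series$values, nrow = prod(d[1:3]), ncol = d[4])
  t(flat[mask$values != 0, , drop = FALSE])
}

#' The default template grid (MNI152, 2 mm)
#'
#' The conventional group-space grid: 91 x 109 x 91 voxels, 2 mm isotropic,
#' world origin at (90, -126, -72) mm.
#'
#' @return A `template_space` list with `shape`, `voxel_size_mm`, `origin_mm`.
#' @export
template_space_default <- function() {
  structure(list(shape = c(91L, 109L, 91L),
                 voxel_size_mm = c(2, 2, 2),
                 origin_mm = c(90, -126, -72)),
            class = "template_space")
}

#' Describe the grid of a mask as a template space
#' @param mask a [mask_volume()].
#' @return A `template_space` for the mask's own grid.
#' @export
template_space_of <- function(mask) {
  structure(list(shape = dim(mask$values),
                 voxel_size_mm = voxel_size(mask),
                 origin_mm = as.numeric(mask$affine[1:3, 4])),
            class = "template_space")
}

#' Validate a mask's grid against a template space
#'
#' Checks conformity of shape, voxel size and world origin against a target
#' space (by default the 2 mm MNI group grid). Reports rather than throws:
#' all three checks must pass (within 1e-3 mm for the metric ones) for the
#' mask to be usable in a group analysis.
#'
#' @param mask a [mask_volume()].
#' @param space a `template_space`; default [template_space_default()].
#' @return A list with logical `ok` and per-check logicals `shape_ok`,
#'   `voxel_size_ok`, `origin_ok`, plus a character vector `messages`.
#' @export
validate_space <- function(mask, space = template_space_default()) {
  tol <- 1e-3
  shape_ok <- identical(as.integer(dim(mask$values)), as.integer(space$shape))
  vs_ok <- all(abs(voxel_size(mask) - space$voxel_size_mm) <= tol)
  or_ok <- all(abs(as.numeric(mask$affine[1:3, 4]) - space$origin_mm) <= tol)
  msgs <- character()
  if (!shape_ok)
    msgs <- c(msgs, sprintf("shape mismatch: %s vs %s",
                            paste(dim(mask$values), collapse = "x"),
                            paste(space$shape, collapse = "x")))
  if (!vs_ok)
    msgs <- c(msgs, sprintf("voxel size mismatch: %s vs %s mm",
                            paste(signif(voxel_size(mask), 4), collapse = "x"),
                            paste(space$voxel_size_mm, collapse = "x")))
  if (!or_ok)
    msgs <- c(msgs, sprintf("origin mismatch: (%s) vs (%s) mm",
                            paste(signif(mask$affine[1:3, 4], 6), collapse = ", "),
                            paste(space$origin_mm, collapse = ", ")))
  list(ok = shape_ok && vs_ok && or_ok, shape_ok = shape_ok,
       voxel_size_ok = vs_ok, origin_ok = or_ok, messages = msgs)
}

#' Affine of the default template grid
#' @param space a `template_space`.
#' @return A 4x4 voxel-to-world matrix with RAS convention (x flipped, as in
#'   the conventional 2 mm group template header).
#' @export
template_affine <- function(space = template_space_default()) {
  a <- diag(4)
  a[1, 1] <- -space$voxel_size_mm[1]
  a[2, 2] <- space$voxel_size_mm[2]
  a[3, 3] <- space$voxel_size_mm[3]
  a[1:3, 4] <- space$origin_mm
  a
}
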