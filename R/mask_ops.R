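# ROI and target mask preprocessing.
#
# All operations take and return mask_volume objects on explicit grids;
# voxel coordinates are 0-based and world distances go through the affine.

.shifted_sum_27 <- function(vals) {
  # sum over the 3x3x3 neighborhood with zero padding outside the grid
  d <- dim(vals)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vals
  s <- array(0L, dim = d)
  for (di in 0:2) for (dj in 0:2) for (dk in 0:2)
    s <- s + pad[(1 + di):(d[1] + di), (1 + dj):(d[2] + dj),
                 (1 + dk):(d[3] + dk)]
  s
}

#' Median-filter a binary mask
#'
#' Replaces each voxel with the median over its 3x3x3 neighborhood (27
#' cells, zero padded at the grid border). On a binary mask this removes
#' isolated voxels and fills single-voxel holes, smoothing ragged ROI
#' edges. The median of 27 binary cells is 1 iff at least 14 are 1.
#'
#' @param mask a [mask_volume()].
#' @return The filtered [mask_volume()]; an empty mask is returned unchanged
#'   with a warning.
#' @export
median_filter_mask <- function(mask) {
  if (sum(mask$values) == 0L) {
    warning("median_filter_mask: mask is empty; returned unchanged")
    return(mask)
  }
  s <- .shifted_sum_27(mask$values)
  mask_volume(array(as.integer(s >= 14L), dim = dim(mask$values)),
              affine = mask$affine)
}

#' Subsample a target mask by parity
#'
#' Keeps only every second voxel in each dimension — a voxel at 0-based
#' grid index (i, j, k) survives iff i, j and k are all even — thinning the
#' target cloud to reduce the feature count while covering the same space.
#' Grid and affine are unchanged.
#'
#' @param target a [mask_volume()].
#' @return The subsampled [mask_volume()].
#' @export
subsample_target <- function(target) {
  d <- dim(target$values)
  keep <- array(0L, dim = d)
  io <- seq(1L, d[1], by = 2L); jo <- seq(1L, d[2], by = 2L)
  ko <- seq(1L, d[3], by = 2L)
  keep[io, jo, ko] <- 1L
  mask_volume(target$values * keep, affine = target$affine)
}

#' Remove the ROI (plus a border) from the target mask
#'
#' Deletes every ROI voxel from the target, and additionally every target
#' voxel whose Euclidean distance (in mm, through the affine) to the nearest
#' ROI voxel is at most `border_mm`. The border guards the connectivity
#' features against spatial-smoothing leakage from the ROI itself.
#'
#' @param target,roi [mask_volume()]s on the same grid (same shape and
#'   affine).
#' @param border_mm non-negative border width in mm; 0 removes only the ROI
#'   voxels themselves.
#' @return The pruned target [mask_volume()].
#' @export
remove_roi_from_target <- function(target, roi, border_mm = 0) {
  stopifnot(border_mm >= 0)
  if (!identical(dim(target$values), dim(roi$values)) ||
      max(abs(target$affine - roi$affine)) > 1e-6)
    stop("target and ROI masks are not on the same grid")
  out <- target$values * (1L - roi$values)
  if (border_mm > 0 && sum(roi$values) > 0L && sum(out) > 0L) {
    roi_mm <- voxel_to_world(mask_coordinates(roi), roi$affine)
    tgt_idx <- which(out != 0)
    tgt_coords <- which(out != 0, arr.ind = TRUE) - 1L
    tgt_mm <- voxel_to_world(tgt_coords, target$affine)
    # min squared distance to any ROI voxel, chunked to bound memory
    keep <- logical(length(tgt_idx))
    r2 <- rowSums(roi_mm^2)
    chunk <- max(1L, floor(2e6 / nrow(roi_mm)))
    for (start in seq(1L, length(tgt_idx), by = chunk)) {
      rows <- start:min(start + chunk - 1L, length(tgt_idx))
      tm <- tgt_mm[rows, , drop = FALSE]
      d2 <- outer(rowSums(tm^2), r2, "+") - 2 * tm %*% t(roi_mm)
      keep[rows] <- sqrt(pmax(apply(d2, 1, min), 0)) > border_mm
    }
    out[tgt_idx[!keep]] <- 0L
  }
  mask_volume(out, affine = target$affine)
}

#' Upsample an ROI mask onto a denser grid without adding voxels
#'
#' Spreads the ROI voxels out equidistantly on a grid `factor` times denser:
#' the voxel at 0-based (i, j, k) moves to (f*i, f*j, f*k). The voxel count
#' is preserved and no two output voxels are 26-connected neighbours, which
#' lets a high-resolution tractography seed set map back one-to-one onto
#' the original ROI voxels. The affine's voxel size is divided by `factor`
#' so each source voxel keeps its world position.
#'
#' @param roi a [mask_volume()].
#' @param factor integer upsampling factor, at least 2.
#' @return A list with `mask` (the upsampled [mask_volume()]) and `mapping`
#'   (an `upsample_mapping` with `source_index`, `upsampled_index`, `factor`,
#'   `source_shape`, `source_affine`).
#' @export
upsample_roi <- function(roi, factor) {
  factor <- as.integer(factor)
  if (factor < 2L) stop("upsampling factor must be >= 2")
  d <- dim(roi$values)
  src <- mask_coordinates(roi)
  up_dim <- (d - 1L) * factor + 1L
  up <- array(0L, dim = up_dim)
  up_idx <- src * factor
  up[up_idx + 1L] <- 1L
  aff <- roi$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] / factor
  mapping <- structure(list(source_index = src, upsampled_index = up_idx,
                            factor = factor, source_shape = d,
                            source_affine = roi$affine),
                       class = "upsample_mapping")
  list(mask = mask_volume(up, affine = aff), mapping = mapping)
}

#' Map voxel values on an upsampled grid back onto the original ROI grid
#'
#' Inverts [upsample_roi()]: values at the upsampled coordinates are placed
#' back at their source coordinates.
#'
#' @param values vector of per-voxel values in `mapping$upsampled_index`
#'   order, or a [mask_volume()] on the upsampled grid.
#' @param mapping the `upsample_mapping` returned by [upsample_roi()].
#' @return A [mask_volume()] on the original grid when given a mask;
#'   otherwise a 3D array of values on the original grid.
#' @export
map_back_roi <- function(values, mapping) {
  if (inherits(values, "mask_volume")) {
    vals <- values$values[mapping$upsampled_index + 1L]
    out <- array(0L, dim = mapping$source_shape)
    out[mapping$source_index + 1L] <- vals
    return(mask_volume(out, affine = mapping$source_affine))
  }
  out <- array(0, dim = mapping$source_shape)
  out[mapping$source_index + 1L] <- values
  out
}

#' Downsample a target mask by block aggregation
#'
#' Aggregates each `factor`^3 block of input voxels into one output voxel,
#' which is set iff at least half of the block's in-grid cells are set —
#' fewer voxels covering the same space. Output grid dimensions are
#' `ceiling(dim / factor)` and the affine's voxel size is multiplied by
#' `factor`.
#'
#' @param target a [mask_volume()].
#' @param factor integer downsampling factor, at least 2.
#' @return The downsampled [mask_volume()].
#' @export
downsample_target <- function(target, factor) {
  factor <- as.integer(factor)
  if (factor < 2L) stop("downsampling factor must be >= 2")
  d <- dim(target$values)
  nd <- as.integer(ceiling(d / factor))
  out <- array(0L, dim = nd)
  block <- function(o, dd) seq((o - 1L) * factor + 1L, min(o * factor, dd))
  for (i in seq_len(nd[1])) for (j in seq_len(nd[2])) for (k in seq_len(nd[3])) {
    cells <- target$values[block(i, d[1]), block(j, d[2]), block(k, d[3])]
    out[i, j, k] <- as.integer(sum(cells) >= length(cells) / 2)
  }
  aff <- target$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * factor
  mask_volume(out, affine = aff)
}
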