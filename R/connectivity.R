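# Per-subject connectivity computation: BOLD preprocessing, voxelwise
# correlation, and the matrix transforms applied before clustering.

.gauss_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  g / sum(g)
}

.conv_axis_matrix <- function(n, kernel) {
  # dense Toeplitz operator for zero-padded 1D convolution along an axis,
  # paired with its row sums for border renormalization
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] +
      kernel[off + r + 1L]
  }
  K
}

.smooth_volume_3d <- function(vol, sigma_vox) {
  d <- dim(vol)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- .conv_axis_matrix(d[ax], .gauss_kernel_1d(sigma_vox[ax]))
    # renormalize truncated rows so a constant field is preserved exactly
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    m <- matrix(v, nrow = d[ax])
    v <- array(K %*% m, dim = d[perm])
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Spatially smooth a BOLD series
#'
#' Applies, per timepoint, a separable 3D Gaussian with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` mm, converted to voxel units via
#' the affine's voxel size. The discrete kernel is normalized to unit sum
#' (renormalized at the grid border), so constant fields pass unchanged.
#' `fwhm_mm = 0` disables smoothing and returns the input untouched.
#'
#' @param series a [bold_series()].
#' @param fwhm_mm full width at half maximum of the kernel, in mm.
#' @return The smoothed [bold_series()].
#' @export
smooth_bold <- function(series, fwhm_mm) {
  if (fwhm_mm < 0) stop("smoothing FWHM must be >= 0")
  if (fwhm_mm == 0) return(series)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / voxel_size(series)
  d <- dim(series$values)
  out <- series$values
  for (t in seq_len(d[4]))
    out[, , , t] <- .smooth_volume_3d(series$values[, , , t], sigma_vox)
  bold_series(out, tr_seconds = series$tr_seconds, affine = series$affine)
}

#' Regress nuisance signals out of a BOLD series
#'
#' Replaces every voxel's time series by its ordinary-least-squares
#' residuals against the confound columns plus an intercept, removing e.g.
#' motion, global white-matter and CSF signals before correlation. A
#' rank-deficient design is handled by the pivoted least-squares solution
#' with a warning.
#'
#' @param series a [bold_series()].
#' @param confounds numeric matrix (timepoints x confounds), as returned by
#'   [read_confounds()].
#' @return The residual [bold_series()].
#' @export
regress_nuisance <- function(series, confounds) {
  d <- dim(series$values)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != d[4])
    stop("confound rows (", nrow(confounds),
         ") do not match timepoints (", d[4], ")")
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning("confound design is rank deficient (rank ", qrX$rank, " of ",
            ncol(X), "); using the pivoted least-squares solution")
  Y <- t(matrix(series$values, nrow = prod(d[1:3]), ncol = d[4]))
  res <- qr.resid(qrX, Y)
  out <- array(t(res), dim = d)
  bold_series(out, tr_seconds = series$tr_seconds, affine = series$affine)
}

#' Expand motion parameters to the 24-regressor set
#'
#' Convenience expansion of 6 rigid-body motion parameters to the common
#' 24-parameter set: the parameters, their one-lag temporal differences
#' (first row zero), and the squares of both.
#'
#' @param motion numeric matrix with 6 columns.
#' @return Numeric matrix with 24 columns.
#' @export
expand_motion_24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("expected 6 motion parameter columns")
  d <- rbind(0, diff(motion))
  out <- cbind(motion, d, motion^2, d^2)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_d"),
                     paste0("mp", 1:6, "_sq"), paste0("mp", 1:6, "_dsq"))
  out
}

#' Band-pass filter a BOLD series
#'
#' Zero-phase (forward-backward) Butterworth band-pass of order 3 between
#' `low_hz` and `high_hz`, the standard way the task-free fluctuation band
#' (conventionally 0.01-0.08 Hz) is isolated. Zero-phase application keeps
#' the filter from shifting the signal in time.
#'
#' @param series a [bold_series()].
#' @param low_hz,high_hz pass-band edges; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)` (the Nyquist frequency).
#' @param order Butterworth order (default 3).
#' @return The filtered [bold_series()].
#' @export
bandpass_bold <- function(series, low_hz, high_hz, order = 3L) {
  nyq <- 1 / (2 * series$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf(
      "infeasible band [%g, %g] Hz for TR = %gs (Nyquist %g Hz)",
      low_hz, high_hz, series$tr_seconds, nyq))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  d <- dim(series$values)
  Y <- matrix(series$values, nrow = prod(d[1:3]), ncol = d[4])
  # the pass band excludes DC, so the mean is removed up front; this also
  # suppresses the start-up transient of the forward-backward pass
  for (v in seq_len(nrow(Y))) {
    y <- Y[v, ] - mean(Y[v, ])
    Y[v, ] <- signal::filtfilt(bf, y)
  }
  bold_series(array(Y, dim = d), tr_seconds = series$tr_seconds,
              affine = series$affine)
}

#' Compute the ROI-to-target functional connectivity matrix
#'
#' Entry (v, t) is the Pearson correlation between ROI voxel v's and target
#' voxel t's time series — voxel v's connectivity fingerprint. Zero-variance
#' series yield a correlation of 0 (with a warning) rather than NA, so the
#' clustering stage never sees missing values.
#'
#' @param roi_series timepoints x ROI-voxels matrix (see [series_matrix()]).
#' @param target_series timepoints x target-voxels matrix.
#' @param voxel_index n x 3 matrix of 0-based ROI voxel coordinates, one per
#'   ROI column.
#' @return A [connectivity_matrix()] with values in \[-1, 1\].
#' @export
compute_fc <- function(roi_series, target_series, voxel_index = NULL) {
  roi_series <- as.matrix(roi_series); target_series <- as.matrix(target_series)
  if (nrow(roi_series) != nrow(target_series))
    stop("ROI and target series have different timepoint counts")
  if (nrow(roi_series) < 3L)
    stop("at least 3 timepoints are required for correlation")
  zero_r <- apply(roi_series, 2, sd) == 0
  zero_t <- apply(target_series, 2, sd) == 0
  r <- suppressWarnings(cor(roi_series, target_series))
  dimnames(r) <- NULL
  if (any(zero_r) || any(zero_t)) {
    warning(sum(zero_r), " ROI and ", sum(zero_t),
            " target series have zero variance; correlations set to 0")
    r[!is.finite(r)] <- 0
  }
  r[zero_r, ] <- 0; r[, zero_t] <- 0
  if (is.null(voxel_index))
    voxel_index <- cbind(seq_len(ncol(roi_series)) - 1L, 0L, 0L)
  connectivity_matrix(r, voxel_index, transform_log = "pearson_r")
}

#' Fisher-Z transform a correlation matrix
#'
#' Elementwise `artanh(r)`, the variance-stabilizing transform for Pearson
#' correlations. `|r|` is clipped to `1 - 1e-15` first so perfectly
#' correlated entries map to a large finite value instead of infinity.
#'
#' @param cm a [connectivity_matrix()] with values in \[-1, 1\].
#' @return The transformed [connectivity_matrix()].
#' @export
fisher_z <- function(cm) {
  v <- cm$values
  if (any(v < -1 | v > 1))
    stop("fisher_z requires values in [-1, 1]")
  v <- sign(v) * pmin(abs(v), 1 - 1e-15)
  cm$values <- atanh(v)
  .append_log(cm, "fisher_z")
}

#' Signed cube-root transform
#'
#' Elementwise `sign(x) * |x|^(1/3)`, the variance-stabilizing transform
#' applied to (heavily skewed) tractography streamline counts after
#' densification.
#'
#' @param cm a [connectivity_matrix()].
#' @return The transformed [connectivity_matrix()].
#' @export
cubic_transform <- function(cm) {
  cm$values <- sign(cm$values) * abs(cm$values)^(1 / 3)
  .append_log(cm, "cubic")
}

#' Reduce connectivity features by principal component analysis
#'
#' Projects the voxel fingerprints onto the leading principal components of
#' the column-centered matrix, fitted on this subject alone. `components`
#' may be an integer count or a variance fraction in (0, 1), in which case
#' the smallest count whose cumulative explained variance reaches the
#' fraction is kept.
#'
#' @param cm a [connectivity_matrix()].
#' @param components integer count, or fraction in (0, 1).
#' @return The reduced [connectivity_matrix()]; the explained-variance
#'   ratios of the kept components are attached as attribute
#'   `"explained_variance_ratio"`.
#' @export
pca_reduce <- function(cm, components) {
  n <- nrow(cm$values); p <- ncol(cm$values)
  pc <- prcomp(cm$values, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  if (components > 0 && components < 1) {
    ncomp <- which(cumsum(evr) >= components - 1e-12)[1]
  } else {
    ncomp <- as.integer(components)
    if (ncomp < 1 || ncomp > min(n, p))
      stop("component count must be in [1, min(rows, cols)] = [1, ",
           min(n, p), "]")
    ncomp <- min(ncomp, ncol(pc$x))
  }
  cm$values <- pc$x[, seq_len(ncomp), drop = FALSE]
  cm <- .append_log(cm, sprintf("pca_%d", ncomp))
  attr(cm, "explained_variance_ratio") <- evr[seq_len(ncomp)]
  cm
}

#' Run the full resting-state connectivity pipeline for one subject
#'
#' Enforces the canonical stage order — smooth, regress, band-pass,
#' correlate, Fisher-Z, PCA — and records each applied stage in the
#' matrix's transform log.
#'
#' @param series a [bold_series()].
#' @param roi,target [mask_volume()]s on the series' grid.
#' @param smoothing_fwhm_mm Gaussian FWHM in mm; 0 skips smoothing.
#' @param confounds optional confound matrix for [regress_nuisance()].
#' @param bandpass optional `list(low_hz =, high_hz =)`.
#' @param fisher_z apply [fisher_z()] to the correlations?
#' @param pca optional component count / variance fraction for
#'   [pca_reduce()].
#' @return A [connectivity_matrix()] (rows ordered by [mask_coordinates()]
#'   of the ROI).
#' @export
rsfmri_connectivity <- function(series, roi, target, smoothing_fwhm_mm = 0,
                                confounds = NULL, bandpass = NULL,
                                fisher_z = FALSE, pca = NULL) {
  log <- character()
  if (smoothing_fwhm_mm > 0) {
    series <- smooth_bold(series, smoothing_fwhm_mm)
    log <- c(log, sprintf("smooth_fwhm_%gmm", smoothing_fwhm_mm))
  }
  if (!is.null(confounds)) {
    series <- regress_nuisance(series, confounds)
    log <- c(log, "nuisance_regressed")
  }
  if (!is.null(bandpass)) {
    series <- bandpass_bold(series, bandpass$low_hz, bandpass$high_hz)
    log <- c(log, sprintf("bandpass_%g_%ghz", bandpass$low_hz,
                          bandpass$high_hz))
  }
  cm <- compute_fc(series_matrix(series, roi), series_matrix(series, target),
                   voxel_index = mask_coordinates(roi))
  cm$transform_log <- c(log, cm$transform_log)
  if (isTRUE(fisher_z)) cm <- fisher_z(cm)
  if (!is.null(pca)) cm <- pca_reduce(cm, pca)
  cm
}
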