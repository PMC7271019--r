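# Synthetic cohorts with planted parcellations.
#
# The generator emulates a multi-subject ROI-to-target connectivity study:
# each planted parcel has a prototype connectivity fingerprint, every
# subject observes prototype + i.i.d. Gaussian noise. Defaults mirror a
# small but realistic desk-scale cohort: 30 subjects, a 500-voxel ROI, 200
# target features, 3 planted parcels, and a separation-to-noise ratio of
# 10 (well-separated parcels, as in a clearly organized region).

#' Design of a planted-parcellation cohort
#'
#' @param roi_shape integer triple; the ROI is the full block of this grid.
#' @param k_true number of planted parcels (>= 2), laid out as contiguous
#'   slabs along the first grid axis.
#' @param n_subjects number of subjects.
#' @param n_targets number of target features (columns).
#' @param prototype_separation scale of the parcel prototype fingerprints;
#'   with unit-norm random prototype directions this is (approximately) the
#'   pairwise prototype distance scale.
#' @param subject_noise_sd standard deviation of the per-subject i.i.d.
#'   Gaussian noise added to each fingerprint entry.
#' @param label_flip_rate fraction of voxels whose label is flipped to a
#'   random other label in [make_noisy_labelings()]; in \[0, 1).
#' @param seed integer seed; all generation is a pure function of the
#'   design including this seed.
#' @return A `planted_design` list, including `parcel_assignment` (planted
#'   label per ROI voxel in [mask_coordinates()] order).
#' @export
planted_design <- function(roi_shape = c(10L, 10L, 5L), k_true = 3L,
                           n_subjects = 30L, n_targets = 200L,
                           prototype_separation = 10, subject_noise_sd = 1,
                           label_flip_rate = 0.05, seed = 1L) {
  stopifnot(k_true >= 2L, prototype_separation >= 0, subject_noise_sd >= 0,
            label_flip_rate >= 0, label_flip_rate < 1)
  n_vox <- prod(roi_shape)
  if (k_true > n_vox) stop("k_true exceeds the ROI voxel count")
  # contiguous slabs along axis 1: parcel of a voxel depends on its i index
  mask <- mask_volume(array(1L, dim = roi_shape),
                      affine = diag(c(2, 2, 2, 1)))
  coords <- mask_coordinates(mask)
  cuts <- floor(seq(0, roi_shape[1], length.out = k_true + 1L))
  assignment <- findInterval(coords[, 1], cuts[-1] - 1e-9) + 1L
  assignment <- pmin(assignment, k_true)
  structure(list(roi_shape = as.integer(roi_shape), k_true = as.integer(k_true),
                 n_subjects = as.integer(n_subjects),
                 n_targets = as.integer(n_targets),
                 prototype_separation = prototype_separation,
                 subject_noise_sd = subject_noise_sd,
                 label_flip_rate = label_flip_rate, seed = as.integer(seed),
                 mask = mask, parcel_assignment = assignment),
            class = "planted_design")
}

.with_seed <- function(seed, expr) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  expr
}

#' Generate a cohort of connectivity matrices with planted parcels
#'
#' Each parcel gets a prototype fingerprint (a unit-norm random direction
#' scaled by `prototype_separation`); each subject's matrix is its voxels'
#' prototypes plus i.i.d. Gaussian noise of sd `subject_noise_sd`.
#'
#' @param design a [planted_design()].
#' @return A list with `matrices` (named list of [connectivity_matrix()]s),
#'   `mask` (the ROI [mask_volume()]) and `planted` (true label per voxel).
#' @export
make_connectivity_cohort <- function(design) {
  .with_seed(design$seed, {
    n_vox <- length(design$parcel_assignment)
    proto <- matrix(rnorm(design$k_true * design$n_targets),
                    nrow = design$k_true)
    proto <- proto / sqrt(rowSums(proto^2)) * design$prototype_separation
    vi <- mask_coordinates(design$mask)
    mats <- lapply(seq_len(design$n_subjects), function(s) {
      base <- proto[design$parcel_assignment, , drop = FALSE]
      noise <- matrix(rnorm(n_vox * design$n_targets,
                            sd = design$subject_noise_sd), nrow = n_vox)
      connectivity_matrix(base + noise, voxel_index = vi,
                          transform_log = "synthetic")
    })
    names(mats) <- sprintf("S%02d", seq_len(design$n_subjects))
    list(matrices = mats, mask = design$mask,
         planted = design$parcel_assignment)
  })
}

#' Generate a cohort of BOLD series with planted parcels
#'
#' Builds `k_true` latent band-limited signals (sums of sinusoids inside
#' 0.01-0.08 Hz with random phases). Each ROI voxel's series is its
#' parcel's signal plus noise; each target voxel is tied to one parcel the
#' same way, so voxelwise correlation recovers the planted structure.
#' Optionally a known confound (linear trend + slow sinusoid) is added to
#' every series and returned, to exercise nuisance regression.
#'
#' @param design a [planted_design()]; `n_targets` target voxels are placed
#'   in grid slabs above the ROI, on the same grid as the ROI (one 4D image
#'   covers both masks, as with real whole-brain data).
#' @param n_timepoints number of timepoints (>= 50).
#' @param tr repetition time in seconds.
#' @param with_confounds add (and return) the known confound pair?
#' @return A list with `series` (one [bold_series()] covering both masks),
#'   `roi_mask`, `target_mask`, `planted`, and `confounds` (matrix or
#'   `NULL`).
#' @export
make_bold_cohort <- function(design, n_timepoints = 200L, tr = 0.72,
                             with_confounds = FALSE) {
  if (n_timepoints < 50L) stop("need at least 50 timepoints")
  .with_seed(design$seed + 1L, {
    tt <- (seq_len(n_timepoints) - 1L) * tr
    freqs <- seq(0.015, 0.075, length.out = 4)
    latent <- vapply(seq_len(design$k_true), function(j) {
      ph <- runif(length(freqs), 0, 2 * pi)
      amp <- runif(length(freqs), 0.5, 1)
      rowSums(vapply(seq_along(freqs), function(f)
        amp[f] * sin(2 * pi * freqs[f] * tt + ph[f]), numeric(n_timepoints)))
    }, numeric(n_timepoints))
    latent <- scale(latent)          # unit-variance latent signals
    conf <- NULL
    conf_signal <- 0
    if (with_confounds) {
      conf <- cbind(trend = seq(-1, 1, length.out = n_timepoints),
                    slow_sine = sin(2 * pi * 0.005 * tt))
      conf_signal <- conf %*% c(2, 1.5)
    }
    sd_n <- design$subject_noise_sd / design$prototype_separation
    roi_lab <- design$parcel_assignment
    n_vox <- length(roi_lab)
    rd <- design$roi_shape
    # shared grid: ROI slab at z <= rd[3], target voxels stacked above it
    tz <- ceiling(design$n_targets / (rd[1] * rd[2]))
    grid_dim <- c(rd[1], rd[2], rd[3] + tz)
    roi_vol <- array(0L, dim = grid_dim)
    roi_vol[, , seq_len(rd[3])] <- design$mask$values
    tgt_vol <- array(0L, dim = grid_dim)
    slab <- array(0L, dim = c(rd[1], rd[2], tz))
    slab[seq_len(design$n_targets)] <- 1L
    tgt_vol[, , rd[3] + seq_len(tz)] <- slab
    aff <- design$mask$affine
    roi_mask <- mask_volume(roi_vol, affine = aff)
    tgt_mask <- mask_volume(tgt_vol, affine = aff)
    tgt_lab <- rep_len(seq_len(design$k_true), design$n_targets)
    roi_ts <- matrix(latent[, roi_lab], nrow = n_timepoints) +
      matrix(rnorm(n_timepoints * n_vox, sd = sd_n), nrow = n_timepoints) +
      as.vector(conf_signal)
    tgt_ts <- matrix(latent[, tgt_lab], nrow = n_timepoints) +
      matrix(rnorm(n_timepoints * design$n_targets, sd = sd_n),
             nrow = n_timepoints) + as.vector(conf_signal)
    flat <- matrix(0, prod(grid_dim), n_timepoints)
    flat[roi_vol != 0, ] <- t(roi_ts)     # column-major == coordinate order
    flat[tgt_vol != 0, ] <- t(tgt_ts)
    vals <- array(flat, dim = c(grid_dim, n_timepoints))
    list(series = bold_series(vals, tr_seconds = tr, affine = aff),
         roi_mask = roi_mask, target_mask = tgt_mask,
         planted = roi_lab, confounds = conf)
  })
}

#' Generate noisy subject labelings of the planted parcellation
#'
#' Each subject starts from the planted labels, its cluster ids are
#' randomly permuted (ids are arbitrary per subject, as in real individual
#' clusterings), and `label_flip_rate` of voxels are flipped to a uniformly
#' random other label.
#'
#' @param design a [planted_design()]; `label_flip_rate` must be below
#'   `0.5 * (k_true - 1) / k_true`, the regime where the planted label
#'   stays the per-voxel majority in expectation.
#' @return A list of [labeling()]s, one per subject.
#' @export
make_noisy_labelings <- function(design) {
  lim <- 0.5 * (design$k_true - 1) / design$k_true
  if (design$label_flip_rate >= lim)
    stop("label_flip_rate must be < ", signif(lim, 3),
         " for k_true = ", design$k_true)
  .with_seed(design$seed + 2L, {
    n_vox <- length(design$parcel_assignment)
    lapply(seq_len(design$n_subjects), function(s) {
      perm <- sample(design$k_true)
      labs <- perm[design$parcel_assignment]
      n_flip <- round(design$label_flip_rate * n_vox)
      if (n_flip > 0) {
        idx <- sample.int(n_vox, n_flip)
        labs[idx] <- vapply(labs[idx], function(l)
          sample(seq_len(design$k_true)[-l], 1L), integer(1))
      }
      # guard: a flip pattern must never silence a label entirely
      for (g in seq_len(design$k_true))
        if (!any(labs == g)) labs[sample.int(n_vox, 1L)] <- g
      labeling(labs, k = design$k_true, subject_id = sprintf("S%02d", s))
    })
  })
}
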