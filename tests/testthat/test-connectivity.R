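# Connectivity computation: preprocessing, correlation, transforms.

make_series <- function(vals, tr = 0.72, vox = c(2, 2, 2)) {
  bold_series(vals, tr_seconds = tr, affine = diag(c(vox, 1)))
}

test_that("smoothing: identity at fwhm 0, constants invariant, impulse peak", {
  set.seed(1)
  vals <- array(rnorm(5 * 5 * 5 * 3), dim = c(5, 5, 5, 3))
  s <- make_series(vals)
  expect_identical(smooth_bold(s, 0)$values, vals)
  expect_error(smooth_bold(s, -1), ">= 0")

  const <- make_series(array(3.7, dim = c(6, 6, 6, 2)))
  expect_equal(smooth_bold(const, 8)$values, const$values, tolerance = 1e-12)

  # unit impulse at the center of a large grid, fwhm 5 mm on 2 mm voxels:
  # peak equals the product over axes of the normalized discrete Gaussian
  # at offset 0
  imp <- array(0, dim = c(15, 15, 15, 2)); imp[8, 8, 8, 1] <- 1
  sm <- smooth_bold(make_series(imp), 5)
  sigma <- 5 / (2 * sqrt(2 * log(2))) / 2     # in voxels
  r <- ceiling(4 * sigma)
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2)); g <- g / sum(g)
  expect_equal(sm$values[8, 8, 8, 1], g[r + 1]^3, tolerance = 1e-12)
  expect_equal(sm$values[8, 8, 9, 1], g[r + 1]^2 * g[r + 2],
               tolerance = 1e-12)
})

test_that("nuisance regression produces orthogonal residuals", {
  set.seed(2)
  n_t <- 40
  vals <- array(rnorm(3 * 2 * 2 * n_t), dim = c(3, 2, 2, n_t))
  s <- make_series(vals)
  conf <- cbind(a = rnorm(n_t), b = seq_len(n_t) / n_t)
  res <- regress_nuisance(s, conf)
  Y <- matrix(res$values, ncol = n_t)
  for (j in 1:2)
    expect_lt(max(abs(Y %*% conf[, j])) / max(abs(Y %*% rnorm(n_t))), 1e-8)

  # confound equal to a voxel's own series -> residual ~ 0 there
  conf2 <- cbind(self = as.vector(vals[1, 1, 1, ]))
  r2 <- regress_nuisance(s, conf2)
  expect_equal(max(abs(r2$values[1, 1, 1, ])), 0, tolerance = 1e-10)

  # constant-only design (duplicates the intercept, hence rank deficient):
  # output is the demeaned series
  expect_warning(r3 <- regress_nuisance(s, matrix(1, n_t, 1)),
                 "rank deficient")
  expect_equal(as.vector(r3$values[2, 1, 2, ]),
               as.vector(scale(vals[2, 1, 2, ], scale = FALSE)),
               tolerance = 1e-12)

  # centered confound orthogonal to a zero-mean series leaves it unchanged
  x <- sin(2 * pi * seq_len(n_t) / n_t)
  y <- cos(2 * pi * seq_len(n_t) / n_t)
  v2 <- array(rep(x, each = 4), dim = c(2, 2, 1, n_t))
  r4 <- regress_nuisance(make_series(v2), cbind(y))
  expect_equal(as.vector(r4$values[1, 1, 1, ]), x, tolerance = 1e-10)

  expect_error(regress_nuisance(s, conf[1:10, ]), "do not match")
  expect_warning(regress_nuisance(s, cbind(conf, conf[, 1])),
                 "rank deficient")
})

test_that("expanded motion set has 24 columns: params, diffs, squares", {
  set.seed(3)
  mp <- matrix(rnorm(60), 10, 6)
  ex <- expand_motion_24(mp)
  expect_equal(ncol(ex), 24)
  expect_equal(ex[, 1:6], mp, ignore_attr = TRUE)
  expect_equal(unname(ex[3, 7]), mp[3, 1] - mp[2, 1])
  expect_equal(ex[, 13:18], mp^2, ignore_attr = TRUE)
})

test_that("band-pass keeps the pass band and kills DC and stop band", {
  tr <- 0.72
  n_t <- 400
  tt <- (seq_len(n_t) - 1) * tr
  amp_of <- function(x, f_hz) {
    # FFT amplitude at the bin closest to f_hz
    sp <- abs(fft(x)) / n_t * 2
    sp[which.min(abs(seq(0, length.out = n_t, by = 1 / (n_t * tr)) - f_hz))]
  }
  mk <- function(x) make_series(array(rep(x, each = 1), c(1, 1, 1, n_t)),
                                tr = tr)
  mid <- sin(2 * pi * 0.04 * tt)
  out <- bandpass_bold(mk(mid), 0.01, 0.08)
  expect_equal(amp_of(as.vector(out$values), 0.04) /
                 amp_of(mid, 0.04), 1, tolerance = 0.05)

  hi <- sin(2 * pi * 0.16 * tt)   # 2x high edge
  outh <- bandpass_bold(mk(hi), 0.01, 0.08)
  expect_lt(amp_of(as.vector(outh$values), 0.16) / amp_of(hi, 0.16), 0.1)

  dc <- rep(5, n_t)
  outd <- bandpass_bold(mk(dc), 0.01, 0.08)
  expect_lt(abs(mean(outd$values)), 1e-6)

  expect_error(bandpass_bold(mk(mid), 0.01, 0.8), "infeasible")
  expect_error(bandpass_bold(mk(mid), 0, 0.08), "infeasible")
})

test_that("compute_fc is Pearson correlation with zero-variance handling", {
  set.seed(4)
  n_t <- 60
  x <- rnorm(n_t)
  roi <- cbind(x, -x, sin(2 * pi * seq_len(n_t) / n_t))
  tgt <- cbind(x, cos(2 * pi * seq_len(n_t) / n_t))
  cm <- compute_fc(roi, tgt)
  expect_equal(cm$values[1, 1], 1)
  expect_equal(cm$values[2, 1], -1)
  expect_lt(abs(cm$values[3, 2]), 1e-10)   # quadrature sinusoids

  # affine rescaling invariance
  cm2 <- compute_fc(sweep(roi, 2, c(2, 3, 0.5), "*") + 7, tgt)
  expect_equal(cm2$values, cm$values, tolerance = 1e-12)

  expect_warning(cmz <- compute_fc(cbind(x, rep(1, n_t)), tgt),
                 "zero variance")
  expect_equal(cmz$values[2, ], c(0, 0))
  expect_error(compute_fc(roi[1:2, ], tgt[1:2, ]), "3 timepoints")
  expect_error(compute_fc(roi, tgt[1:10, ]), "different timepoint")
})

test_that("fisher_z and cubic transforms are exact, clipped, logged", {
  vi <- cbind(0:2, 0L, 0L)
  cm <- connectivity_matrix(matrix(c(0, 0.5, 1, -1, 0.9, -0.3), 3, 2), vi)
  fz <- fisher_z(cm)
  expect_equal(fz$values[1, 1], 0)
  expect_equal(fz$values[2, 1], 0.5493061443, tolerance = 1e-10)
  expect_true(all(is.finite(fz$values)))   # r = +-1 clipped, not infinite
  expect_identical(fz$transform_log, "fisher_z")
  bad <- connectivity_matrix(matrix(1.5, 1, 1), cbind(0L, 0L, 0L))
  expect_error(fisher_z(bad), "\\[-1, 1\\]")

  cb <- cubic_transform(connectivity_matrix(
    matrix(c(8, 0, -27, 1), 2, 2), cbind(0:1, 0L, 0L)))
  expect_equal(cb$values, matrix(c(2, 0, -3, 1), 2, 2))
  expect_identical(cb$transform_log, "cubic")

  # both transforms are odd and strictly monotone
  xs <- seq(-0.99, 0.99, length.out = 21)
  f <- fisher_z(connectivity_matrix(matrix(xs, ncol = 1),
                                    cbind(seq_along(xs) - 1L, 0L, 0L)))
  expect_equal(f$values, -fisher_z(connectivity_matrix(
    matrix(-xs, ncol = 1), cbind(seq_along(xs) - 1L, 0L, 0L)))$values)
  expect_true(all(diff(f$values[, 1]) > 0))
  g <- cubic_transform(connectivity_matrix(
    matrix(seq(-5, 5, 0.5), ncol = 1), cbind(0:20, 0L, 0L)))
  expect_true(all(diff(g$values[, 1]) > 0))
})

test_that("pca_reduce matches an eigendecomposition oracle up to sign", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30, 8)
  vi <- cbind(0:29, 0L, 0L)
  cm <- connectivity_matrix(X, vi)

  red <- pca_reduce(cm, 3)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  oracle_scores <- Xc %*% ev$vectors[, 1:3]
  for (j in 1:3)
    expect_equal(abs(red$values[, j]), abs(oracle_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(red$voxel_index, cm$voxel_index)

  # rank-1 input, 1 component: perfect reconstruction
  r1 <- tcrossprod(rnorm(20), rnorm(6))
  red1 <- pca_reduce(connectivity_matrix(r1, cbind(0:19, 0L, 0L)), 1)
  ctr <- scale(r1, center = TRUE, scale = FALSE)
  recon <- red1$values %*% t(prcomp(r1)$rotation[, 1, drop = FALSE])
  expect_equal(recon, unclass(ctr), tolerance = 1e-9, ignore_attr = TRUE)

  # all components: 100% variance
  full <- pca_reduce(cm, min(dim(X)))
  expect_equal(sum(attr(full, "explained_variance_ratio")), 1,
               tolerance = 1e-9)

  # variance-fraction request
  frac <- pca_reduce(cm, 0.5)
  evr <- attr(frac, "explained_variance_ratio")
  expect_gte(sum(evr), 0.5)
  expect_error(pca_reduce(cm, 99), "component count")
})

test_that("the rsfmri pipeline applies stages in canonical order", {
  d <- planted_design(roi_shape = c(4L, 3L, 2L), k_true = 2L,
                      n_subjects = 1L, n_targets = 20L, seed = 6)
  b <- make_bold_cohort(d, n_timepoints = 120, with_confounds = TRUE)
  cm <- rsfmri_connectivity(b$series, b$roi_mask, b$target_mask,
                            smoothing_fwhm_mm = 4, confounds = b$confounds,
                            bandpass = list(low_hz = 0.01, high_hz = 0.08),
                            fisher_z = TRUE, pca = 5)
  expect_equal(cm$transform_log,
               c("smooth_fwhm_4mm", "nuisance_regressed",
                 "bandpass_0.01_0.08hz", "pearson_r", "fisher_z", "pca_5"))
  expect_equal(nrow(cm$values), sum(b$roi_mask$values))
})
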