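# Shared fixture builders and brute-force oracles.

nifti_values <- function(path) {
  a <- RNifti::readNifti(path)
  array(as.vector(a), dim = dim(a))
}

random_mask <- function(shape, p = 0.4, seed = 1, affine = diag(c(2, 2, 2, 1))) {
  set.seed(seed)
  mask_volume(array(rbinom(prod(shape), 1, p), dim = shape), affine = affine)
}

# exhaustive 27-cell median (independent of the shifted-sum implementation)
oracle_median_filter <- function(vals) {
  d <- dim(vals)
  out <- array(0L, dim = d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    cells <- integer(0)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ii <- i + di; jj <- j + dj; kk <- k + dk
      cells <- c(cells,
                 if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
                     kk >= 1 && kk <= d[3]) vals[ii, jj, kk] else 0L)
    }
    out[i, j, k] <- as.integer(median(cells))
  }
  out
}

# per-voxel minimum mm distance to the ROI, by exhaustive scan
oracle_border_removal <- function(target, roi, border_mm) {
  roi_mm <- voxel_to_world(mask_coordinates(roi), roi$affine)
  out <- target$values * (1L - roi$values)
  idx <- which(out != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- voxel_to_world(matrix(idx[r, ] - 1L, ncol = 3), target$affine)
    dmin <- sqrt(min(colSums((t(roi_mm) - as.vector(p))^2)))
    if (dmin <= border_mm) out[idx[r, , drop = FALSE]] <- 0L
  }
  out
}

# exhaustive search over all k! id permutations
oracle_relabel_accuracy <- function(subject, reference, k) {
  perms <- perms_of(k)
  best <- 0
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    best <- max(best, mean(p[subject] == reference))
  }
  best
}

perms_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1, function(p) append(p, k, after = pos - 1L)))
  }))
}

# direct-formula indices on raw matrices (O(n^2) loops, no shared code)
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g)
      mean(D[i, labels == g]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_ch <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    ctr <- colMeans(Xg)
    B <- B + nrow(Xg) * sum((ctr - grand)^2)
    for (r in seq_len(nrow(Xg))) W <- W + sum((Xg[r, ] - ctr)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

oracle_db <- function(X, labels) {
  groups <- sort(unique(labels)); k <- length(groups)
  ctr <- lapply(groups, function(g) colMeans(X[labels == g, , drop = FALSE]))
  s <- vapply(seq_len(k), function(i) {
    Xg <- X[labels == groups[i], , drop = FALSE]
    mean(apply(Xg, 1, function(r) sqrt(sum((r - ctr[[i]])^2))))
  }, numeric(1))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / sqrt(sum((ctr[[i]] - ctr[[j]])^2)), numeric(1)))
  }, numeric(1)))
}

random_labels <- function(n, k, seed) {
  set.seed(seed)
  repeat {
    l <- sample.int(k, n, replace = TRUE)
    if (length(unique(l)) == k) return(l)
  }
}

# a ready-to-run connectivity-modality project in a temp dir
make_fixture_project <- function(dir, n_subjects = 4, k_range = c(2L, 3L),
                                 seed = 11) {
  d <- planted_design(roi_shape = c(5L, 4L, 3L), k_true = 2L,
                      n_subjects = n_subjects, n_targets = 30L, seed = seed)
  co <- make_connectivity_cohort(d)
  data_dir <- file.path(dir, "data")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  write_mask(co$mask, file.path(data_dir, "roi.nii.gz"))
  for (s in names(co$matrices))
    write_dense_connectivity(co$matrices[[s]],
                             file.path(data_dir,
                                       sprintf("%s_connectivity.bin", s)))
  write_participants(names(co$matrices),
                     file.path(data_dir, "participants.tsv"))
  cfg <- example_config("connectivity")
  cfg$data$participants <- file.path(data_dir, "participants.tsv")
  cfg$data$roi_mask <- file.path(data_dir, "roi.nii.gz")
  cfg$data$connectivity <- file.path(data_dir,
                                     "{participant_id}_connectivity.bin")
  cfg$masks$validate_space <- FALSE
  cfg$clustering$k_range <- k_range
  cfg$clustering$n_init <- 5L
  cfg$clustering$max_iter <- 100L
  cfg_path <- file.path(dir, "config.yaml")
  write_config(cfg, cfg_path)
  list(config = cfg_path, cohort = co, design = d)
}
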