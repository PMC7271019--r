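# Internal cluster-validity indices and partition-similarity metrics.

.as_labels <- function(x) {
  if (inherits(x, "labeling")) x$labels else as.integer(x)
}

.as_matrix_values <- function(x) {
  if (inherits(x, "connectivity_matrix")) x$values else as.matrix(x)
}

.check_k_range <- function(labels, n) {
  k <- length(unique(labels))
  if (k < 2L || k >= n)
    stop("validity indices require 2 <= k < n (k = ", k, ", n = ", n, ")")
  k
}

#' Mean Silhouette index
#'
#' For each voxel, `a` is its mean Euclidean distance to the other members
#' of its own cluster and `b` the smallest mean distance to any other
#' cluster; its silhouette is `(b - a) / max(a, b)` (0 for members of
#' singleton clusters). The index is the mean over voxels; higher is
#' better, range \[-1, 1\].
#'
#' @param cm a [connectivity_matrix()] or plain matrix (voxels x features).
#' @param lab a [labeling()] or integer label vector.
#' @return Scalar in \[-1, 1\].
#' @export
silhouette_index <- function(cm, lab) {
  X <- .as_matrix_values(cm); labels <- .as_labels(lab)
  n <- nrow(X)
  .check_k_range(labels, n)
  D <- as.matrix(dist(X))
  groups <- sort(unique(labels))
  sizes <- table(factor(labels, levels = groups))
  # mean distance from every voxel to every cluster, in one matrix product
  M <- vapply(groups, function(g) rowSums(D[, labels == g, drop = FALSE]),
              numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- match(labels[i], groups)
    ni <- sizes[g]
    if (ni == 1L) { s[i] <- 0; next }
    a <- M[i, g] / (ni - 1L)
    b <- min(M[i, -g] / sizes[-g])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' The ratio of between-cluster to within-cluster dispersion,
#' `[B / (k - 1)] / [W / (n - k)]`, with both sums of squares taken about
#' centroids. Higher is better. A zero within-cluster dispersion (all
#' members on their centroid) yields a capped sentinel value with a
#' warning so batch reports can complete.
#'
#' @inheritParams silhouette_index
#' @return Non-negative scalar.
#' @export
calinski_harabasz <- function(cm, lab) {
  X <- .as_matrix_values(cm); labels <- .as_labels(lab)
  n <- nrow(X)
  k <- .check_k_range(labels, n)
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    ctr <- colMeans(Xg)
    B <- B + nrow(Xg) * sum((ctr - grand)^2)
    W <- W + sum(sweep(Xg, 2, ctr)^2)
  }
  if (W == 0) {
    warning("zero within-cluster dispersion: Calinski-Harabasz index is ",
            "unbounded; returning the sentinel .Machine$double.xmax")
    return(.Machine$double.xmax)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#'
#' For each cluster, the worst-case ratio `(s_i + s_j) / d_ij` over other
#' clusters, where `s` is the mean distance of members to their centroid
#' and `d` the distance between centroids; the index is the mean over
#' clusters. Lower is better. Coincident centroids yield a capped sentinel
#' with a warning.
#'
#' @inheritParams silhouette_index
#' @return Non-negative scalar.
#' @export
davies_bouldin <- function(cm, lab) {
  X <- .as_matrix_values(cm); labels <- .as_labels(lab)
  n <- nrow(X)
  .check_k_range(labels, n)
  groups <- sort(unique(labels))
  k <- length(groups)
  centroids <- do.call(rbind, lapply(groups, function(g)
    colMeans(X[labels == g, , drop = FALSE])))
  s <- vapply(seq_len(k), function(i) {
    Xg <- X[labels == groups[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xg, 2, centroids[i, ])^2)))
  }, numeric(1))
  Dc <- as.matrix(dist(centroids))
  if (any(Dc[upper.tri(Dc)] == 0)) {
    warning("coincident cluster centroids: Davies-Bouldin index is ",
            "unbounded; returning the sentinel .Machine$double.xmax")
    return(.Machine$double.xmax)
  }
  r <- vapply(seq_len(k), function(i)
    max(vapply(seq_len(k)[-i], function(j) (s[i] + s[j]) / Dc[i, j],
               numeric(1))), numeric(1))
  mean(r)
}

.contingency <- function(a, b) {
  table(factor(a), factor(b))
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions,
#' `(RI - E[RI]) / (max RI - E[RI])` from the contingency table; 1 for
#' identical partitions (up to label permutation), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar, at most 1.
#' @export
ari <- function(a, b) {
  a <- .as_labels(a); b <- .as_labels(b)
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- .contingency(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' V-measure
#'
#' Harmonic mean of homogeneity (`1 - H(a|b) / H(a)`) and completeness
#' (`1 - H(b|a) / H(b)`); 1 for identical partitions, 0 when either side
#' carries no information about the other.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
v_measure <- function(a, b) {
  a <- .as_labels(a); b <- .as_labels(b)
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- as.matrix(.contingency(a, b))
  n <- sum(tab)
  Ha <- .entropy(rowSums(tab)); Hb <- .entropy(colSums(tab))
  # conditional entropies from the joint table
  Hab <- -sum(vapply(seq_len(ncol(tab)), function(j) {
    col <- tab[, j]; nz <- col > 0
    sum(col[nz] / n * log(col[nz] / sum(col)))
  }, numeric(1)))
  Hba <- -sum(vapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]; nz <- row > 0
    sum(row[nz] / n * log(row[nz] / sum(row)))
  }, numeric(1)))
  hom <- if (Ha == 0) 1 else 1 - Hab / Ha
  com <- if (Hb == 0) 1 else 1 - Hba / Hb
  if (hom + com == 0) return(0)
  2 * hom * com / (hom + com)
}

.mutual_information <- function(tab) {
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0)
      mi <- mi + nij / n * log(nij * n / (sum(tab[i, ]) * sum(tab[, j])))
  }
  mi
}

.expected_mi <- function(a_counts, b_counts, n) {
  # exact expectation of MI under the permutation (hypergeometric) model
  emi <- 0
  for (ai in a_counts) for (bj in b_counts) {
    lo <- max(1, ai + bj - n); hi <- min(ai, bj)
    if (hi < lo) next
    for (nij in lo:hi) {
      term <- nij / n * log(n * nij / (ai * bj))
      lp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
      emi <- emi + term * exp(lp)
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information between two partitions, corrected for chance under
#' the permutation model and normalized by the arithmetic mean of the two
#' entropies: `(MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`. 1 for identical
#' partitions; approximately 0 in expectation for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar, at most 1.
#' @export
ami <- function(a, b) {
  a <- .as_labels(a); b <- .as_labels(b)
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- as.matrix(.contingency(a, b))
  n <- sum(tab)
  ac <- rowSums(tab); bc <- colSums(tab)
  Ha <- .entropy(ac); Hb <- .entropy(bc)
  mi <- .mutual_information(tab)
  emi <- .expected_mi(ac, bc, n)
  denom <- (Ha + Hb) / 2 - emi
  if (abs(denom) < 1e-15) return(if (abs(mi - emi) < 1e-15) 1 else 0)
  (mi - emi) / denom
}

.similarity_fun <- function(metric) {
  switch(metric, ari = ari, v_measure = v_measure, ami = ami,
         stop("unknown similarity metric '", metric, "'"))
}

#' Internal validity table for a set of subject clusterings
#'
#' Computes the selected internal indices per (subject, k), each on that
#' subject's own connectivity matrix — scores are comparable within the
#' sample only and are never pooled across subjects' feature spaces.
#'
#' @param matrices named list of per-subject [connectivity_matrix()]s.
#' @param labelings_by_k list indexed by k of lists of per-subject
#'   [labeling()]s aligned with `matrices`.
#' @param metrics subset of `c("silhouette", "calinski_harabasz",
#'   "davies_bouldin")`.
#' @return A data.frame with columns `subject_id`, `k` and one per metric.
#' @export
validity_table <- function(matrices, labelings_by_k,
                           metrics = c("silhouette", "calinski_harabasz",
                                       "davies_bouldin")) {
  fun <- list(silhouette = silhouette_index,
              calinski_harabasz = calinski_harabasz,
              davies_bouldin = davies_bouldin)
  rows <- list()
  for (kname in names(labelings_by_k)) {
    labs <- labelings_by_k[[kname]]
    for (i in seq_along(labs)) {
      lab <- labs[[i]]
      sid <- if (nzchar(lab$subject_id)) lab$subject_id else names(matrices)[i]
      row <- data.frame(subject_id = sid, k = lab$k)
      for (m in metrics) row[[m]] <- fun[[m]](matrices[[i]], lab)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Pairwise similarity of subject clusterings, and similarity to the group
#'
#' Builds the subject-by-subject similarity matrix under the chosen metric
#' plus each subject's similarity to the group labeling, and a hierarchical
#' tree over subjects built from `1 - similarity`. The similarity to the
#' group is reported with the caveat that the group labeling is derived
#' from the very clusterings it is compared against, which can inflate the
#' scores.
#'
#' @param labelings list of per-subject [labeling()]s (same voxel set).
#' @param group integer group labels over the same voxels.
#' @param metric `"ari"`, `"v_measure"` or `"ami"`.
#' @param linkage linkage for the subject dendrogram.
#' @return A `similarity_report` list: `metric`, `pairwise` (subject matrix),
#'   `to_group` (named vector), `tree` (`hclust` over subjects), `caveat`.
#' @export
similarity_report <- function(labelings, group, metric = "ari",
                              linkage = "average") {
  if (length(labelings) < 2L) stop("similarity report needs >= 2 subjects")
  f <- .similarity_fun(metric)
  S <- length(labelings)
  ids <- vapply(seq_len(S), function(i) {
    l <- labelings[[i]]
    if (inherits(l, "labeling") && nzchar(l$subject_id)) l$subject_id
    else paste0("subject", i)
  }, "")
  P <- matrix(1, S, S, dimnames = list(ids, ids))
  for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
    P[i, j] <- P[j, i] <- f(labelings[[i]], labelings[[j]])
  }
  to_group <- vapply(labelings, f, numeric(1), b = group)
  names(to_group) <- ids
  d <- 1 - P
  d[d < 0] <- 0
  tree <- hclust(as.dist(d), method = linkage)
  structure(list(metric = metric, pairwise = P, to_group = to_group,
                 tree = tree,
                 caveat = paste("group similarity is not independent of the",
                                "individual subject clusterings")),
            class = "similarity_report")
}

#' Save the subject dendrogram of a similarity report
#' @param report a `similarity_report`.
#' @param path output figure path (`.png` or `.pdf`).
#' @return `path`, invisibly.
#' @export
plot_similarity_dendrogram <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdf") pdf(path, width = 7, height = 5)
  else png(path, width = 900, height = 600)
  on.exit(dev.off())
  plot(as.dendrogram(report$tree),
       main = sprintf("Subject clustering similarity (1 - %s)",
                      report$metric),
       ylab = sprintf("1 - %s", report$metric))
  invisible(path)
}

#' Compare a group parcellation against a reference label image
#'
#' Similarity between the group labels and an external reference labeling
#' (e.g. a histological parcellation of the same region) over the ROI
#' voxels, plus the mismatched-voxel count after optimal permutation
#' alignment of the label ids (counting without alignment would depend on
#' arbitrary ids).
#'
#' @param group integer group labels over ROI voxels.
#' @param reference integer reference labels over the same voxels (e.g.
#'   from [read_label_image()]).
#' @param metric `"ari"` (default), `"v_measure"` or `"ami"`.
#' @return A list with `similarity`, `metric`, `n_mismatch`,
#'   `pct_mismatch`, `n_voxels`.
#' @export
compare_reference <- function(group, reference, metric = "ari") {
  group <- .as_labels(group); reference <- .as_labels(reference)
  if (length(group) != length(reference))
    stop("group and reference cover different voxel counts")
  if (any(reference < 1L))
    stop("reference labels must cover all ROI voxels with labels >= 1")
  f <- .similarity_fun(metric)
  al <- relabel(group, reference)
  list(similarity = f(group, reference), metric = metric,
       n_mismatch = sum(al$labels != reference),
       pct_mismatch = 100 * mean(al$labels != reference),
       n_voxels = length(group))
}
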