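# Group-level consensus: Hamming-distance reference, permutation
# relabeling, mode aggregation, cophenetic correlation.

.labels_matrix <- function(labelings) {
  # subjects x voxels integer matrix from a list of labelings
  if (length(labelings) == 0L) stop("no labelings given")
  rows <- lapply(labelings, function(l)
    if (inherits(l, "labeling")) l$labels else as.integer(l))
  n <- unique(lengths(rows))
  if (length(n) != 1L)
    stop("labelings cover inconsistent voxel counts: ",
         paste(unique(lengths(rows)), collapse = ", "))
  do.call(rbind, rows)
}

#' Voxel-by-voxel Hamming distance across subjects
#'
#' `d(u, v)` is the fraction of subjects in which voxels u and v carry
#' different cluster labels. Because only *co-assignment* of voxel pairs
#' enters, the distance is invariant to each subject's arbitrary cluster
#' ids — which is exactly why it can anchor the group reference before any
#' relabeling has happened.
#'
#' @param labelings list of [labeling()]s (or integer vectors) over the same
#'   voxel set.
#' @return Symmetric voxels x voxels matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
hamming_matrix <- function(labelings) {
  L <- .labels_matrix(labelings)
  n <- ncol(L); S <- nrow(L)
  D <- matrix(0, n, n)
  for (s in seq_len(S)) {
    ls <- L[s, ]
    D <- D + (outer(ls, ls, "!=") * 1)
  }
  D / S
}

#' Hierarchical reference clustering of the Hamming matrix
#'
#' Builds an agglomerative tree on the voxel-by-voxel distance matrix and
#' cuts it at k clusters. The cut serves as the reference labeling against
#' which every subject is relabeled.
#'
#' @param distance symmetric voxels x voxels distance matrix.
#' @param k number of clusters.
#' @param linkage linkage method (default `"complete"`).
#' @return A list with `labels` (integer reference labels, 1..k) and `tree`
#'   (the `hclust` object).
#' @export
reference_clustering <- function(distance, k, linkage = "complete") {
  distance <- as.matrix(distance)
  if (k > nrow(distance))
    stop("k = ", k, " exceeds the number of voxels (", nrow(distance), ")")
  method <- if (identical(linkage, "ward")) "ward.D2" else linkage
  tree <- hclust(as.dist(distance), method = method)
  labels <- cutree(tree, k = k)
  list(labels = as.integer(labels), tree = tree)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                   sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

.best_permutation <- function(C) {
  # permutation p maximizing sum_i C[i, p[i]] on the k x k contingency table
  k <- nrow(C)
  if (k <= 8L) {
    perms <- .permutations(k)
    scores <- apply(perms, 1, function(p) sum(C[cbind(seq_len(k), p)]))
    perms[which.max(scores), ]
  } else {
    g <- igraph::make_bipartite_graph(
      rep(c(TRUE, FALSE), each = k),
      as.vector(rbind(rep(seq_len(k), each = k),
                      rep(seq_len(k) + k, times = k))))
    w <- as.vector(t(C)) + 1    # +1 keeps zero-count edges matchable
    m <- igraph::max_bipartite_match(g, weights = w)
    as.integer(m$matching[seq_len(k)] - k)
  }
}

#' Relabel a subject against the reference
#'
#' Finds the bijection of cluster ids that maximizes the fraction of voxels
#' on which the permuted subject labeling agrees with the reference
#' (exhaustive over all k! permutations for k <= 8, maximum-weight
#' bipartite matching on the contingency table otherwise — the two are
#' equivalent).
#'
#' @param subject a [labeling()] or integer label vector.
#' @param reference integer reference labels (1..k).
#' @return A list with `labels` (permuted subject labels), `accuracy` (the
#'   maximal agreement fraction) and `permutation` (new id of each old id).
#' @export
relabel <- function(subject, reference) {
  s <- if (inherits(subject, "labeling")) subject$labels else as.integer(subject)
  reference <- as.integer(reference)
  if (length(s) != length(reference))
    stop("subject and reference cover different voxel counts")
  k <- max(s, reference)
  if (inherits(subject, "labeling") && subject$k != length(unique(reference)))
    stop("subject k (", subject$k, ") does not match reference k (",
         length(unique(reference)), ")")
  C <- matrix(0, k, k)
  tab <- table(factor(s, levels = 1:k), factor(reference, levels = 1:k))
  C[] <- as.numeric(tab)
  perm <- .best_permutation(C)
  new_labels <- perm[s]
  list(labels = as.integer(new_labels),
       accuracy = mean(new_labels == reference),
       permutation = perm)
}

#' Per-voxel mode across relabeled subjects
#'
#' The group labeling: each voxel gets its most frequent label across
#' subjects. Ties are broken toward the smallest label id; the number of
#' tied voxels is reported via a message.
#'
#' @param relabeled subjects x voxels integer matrix (or list of label
#'   vectors) with comparable ids, i.e. after [relabel()].
#' @return Integer vector of mode labels.
#' @export
mode_consensus <- function(relabeled) {
  if (is.list(relabeled)) relabeled <- .labels_matrix(relabeled)
  if (length(relabeled) == 0L) stop("empty relabeled matrix")
  kmax <- max(relabeled)
  n_ties <- 0L
  modes <- apply(relabeled, 2, function(v) {
    counts <- tabulate(v, nbins = kmax)
    best <- which(counts == max(counts))
    if (length(best) > 1L) n_ties <<- n_ties + 1L
    best[1]
  })
  if (n_ties > 0L)
    .rcbp_log(n_ties, " voxel(s) had tied mode counts; ",
              "smallest label id used")
  as.integer(modes)
}

#' Cophenetic correlation of a hierarchical tree
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic (dendrogram merge-height) distances — how faithfully the tree
#' preserves the pairwise structure it was built from.
#'
#' @param tree an `hclust` object.
#' @param distance the distance matrix the tree was built from.
#' @return Scalar in \[-1, 1\]; `NaN` with a warning when either distance
#'   set has zero variance.
#' @export
cophenetic_r <- function(tree, distance) {
  d0 <- as.dist(as.matrix(distance))
  if (attr(d0, "Size") < 3L) stop("cophenetic correlation needs >= 3 voxels")
  dc <- cophenetic(tree)
  if (sd(d0) == 0 || sd(dc) == 0) {
    warning("constant distances: cophenetic correlation undefined (NaN)")
    return(NaN)
  }
  cor(as.vector(d0), as.vector(dc))
}

#' Group-level parcellation from individual labelings
#'
#' Orchestrates the consensus pipeline for one k: Hamming distance matrix
#' over voxels, hierarchical reference clustering, optimal permutation
#' relabeling of every subject, and per-voxel mode aggregation (or, when
#' `group_mode = "hierarchical"`, the reference cut itself as the group
#' labeling).
#'
#' @param labelings list of [labeling()]s, one per subject, same voxel set
#'   and k (at least 2 subjects).
#' @param k number of clusters.
#' @param linkage linkage for the reference tree (default `"complete"`).
#' @param group_mode `"mode"` (default) or `"hierarchical"`.
#' @return A `group_result` list: `k`, `reference_labels`, `relabeled`
#'   (subjects x voxels matrix), `relabel_accuracy` (named per subject),
#'   `mode_labels`, `cophenetic_r`, `group_mode`, `tree`.
#' @export
group_parcellation <- function(labelings, k, linkage = "complete",
                               group_mode = c("mode", "hierarchical")) {
  group_mode <- match.arg(group_mode)
  if (length(labelings) < 2L)
    stop("group parcellation needs at least 2 subjects")
  D <- hamming_matrix(labelings)
  ref <- reference_clustering(D, k = k, linkage = linkage)
  res <- lapply(labelings, relabel, reference = ref$labels)
  relabeled <- do.call(rbind, lapply(res, `[[`, "labels"))
  acc <- vapply(res, `[[`, numeric(1), "accuracy")
  ids <- vapply(seq_along(labelings), function(i) {
    l <- labelings[[i]]
    if (inherits(l, "labeling") && nzchar(l$subject_id)) l$subject_id
    else paste0("subject", i)
  }, "")
  names(acc) <- ids
  rownames(relabeled) <- ids
  mode_labels <- if (group_mode == "hierarchical") ref$labels
                 else mode_consensus(relabeled)
  structure(list(k = as.integer(k), reference_labels = ref$labels,
                 relabeled = relabeled, relabel_accuracy = acc,
                 mode_labels = mode_labels,
                 cophenetic_r = cophenetic_r(ref$tree, D),
                 group_mode = group_mode, tree = ref$tree),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(paste0("<group_result> k = %d, %d subjects, %d voxels\n",
                     "  group labeling: %s; mean relabel accuracy %.3f; ",
                     "cophenetic r %.3f\n"),
              x$k, nrow(x$relabeled), ncol(x$relabeled), x$group_mode,
              mean(x$relabel_accuracy), x$cophenetic_r))
  invisible(x)
}
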