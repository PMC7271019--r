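# Individual-level hard clustering of connectivity fingerprints.

#' Clustering parameter set
#'
#' Defaults follow the standard voxel-parcellation practice: k-means with
#' k-means++ seeding, 256 restarts and up to 10,000 Lloyd iterations per
#' restart; best restart selected by within-cluster sum of squares.
#'
#' @param method `"kmeans"`, `"spectral"` or `"agglomerative"`.
#' @param k number of clusters, at least 2.
#' @param n_init number of random restarts (k-means only).
#' @param max_iter iteration cap per restart.
#' @param init_method `"k-means++"` or `"random"`.
#' @param linkage agglomerative linkage (default `"complete"`).
#' @param n_neighbors neighbourhood size of the spectral affinity graph.
#' @param seed integer RNG seed; results are deterministic given the seed.
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(method = "kmeans", k = 2L, n_init = 256L,
                           max_iter = 10000L, init_method = "k-means++",
                           linkage = "complete", n_neighbors = 10L,
                           seed = 1L) {
  stopifnot(method %in% c("kmeans", "spectral", "agglomerative"),
            k >= 2L, n_init >= 1L, max_iter >= 1L,
            init_method %in% c("k-means++", "random"))
  structure(list(method = method, k = as.integer(k),
                 n_init = as.integer(n_init), max_iter = as.integer(max_iter),
                 init_method = init_method, linkage = linkage,
                 n_neighbors = as.integer(n_neighbors),
                 seed = as.integer(seed)),
            class = "cluster_params")
}

#' Construct a labeling
#' @param labels integer vector of cluster labels in 1..k.
#' @param k number of clusters.
#' @param subject_id subject identifier.
#' @param params the `cluster_params` used (optional).
#' @return A `labeling` object.
#' @export
labeling <- function(labels, k, subject_id = "", params = NULL) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (any(labels < 1L | labels > k))
    stop("labels outside 1..k")
  if (length(unique(labels)) < k)
    stop("not all ", k, " labels occur in the labeling")
  structure(list(labels = labels, k = k, subject_id = subject_id,
                 params = params), class = "labeling")
}

#' @export
print.labeling <- function(x, ...) {
  cat(sprintf("<labeling> subject '%s', %d voxels, k = %d\n",
              x$subject_id, length(x$labels), x$k))
  invisible(x)
}

.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) centers[j] <- sample.int(n, 1L)
    else centers[j] <- sample.int(n, 1L, prob = d2)
    dj <- rowSums((X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  X[centers, , drop = FALSE]
}

.kmeans_once <- function(X, k, init_method, max_iter) {
  for (attempt in 1:25) {
    C <- if (init_method == "k-means++") .kmeanspp_centers(X, k)
         else X[sample.int(nrow(X), k), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(kmeans(X, centers = C, iter.max = max_iter,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    # a run that dropped a cluster is re-initialized, never returned
    if (!is.null(fit) && length(unique(fit$cluster)) == k) return(fit)
  }
  stop("k-means failed to produce ", k, " non-empty clusters after 25 ",
       "re-initializations; is k larger than the number of distinct rows?")
}

.cluster_kmeans <- function(X, params) {
  best <- NULL
  for (i in seq_len(params$n_init)) {
    fit <- .kmeans_once(X, params$k, params$init_method, params$max_iter)
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster
}

.cluster_agglomerative <- function(X, params) {
  method <- params$linkage
  if (identical(method, "ward")) method <- "ward.D2"
  cutree(hclust(dist(X), method = method), k = params$k)
}

.cluster_spectral <- function(X, params) {
  n <- nrow(X)
  k <- params$k
  nn <- min(params$n_neighbors, n - 1L)
  D <- as.matrix(dist(X))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(nn + 1L)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))                      # mutual-or symmetrization
  deg <- pmax(rowSums(A), .Machine$double.eps)
  Dm <- 1 / sqrt(deg)
  L <- diag(n) - (Dm * A) * rep(Dm, each = n)   # normalized Laplacian
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, n - seq_len(k) + 1L, drop = FALSE]  # k smallest
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  sub <- cluster_params(method = "kmeans", k = k,
                        n_init = max(10L, params$n_init %/% 8L),
                        max_iter = params$max_iter, seed = params$seed)
  .cluster_kmeans(U, sub)
}

#' Cluster one subject's connectivity matrix
#'
#' Partitions the ROI voxels into `params$k` parcels by their connectivity
#' fingerprints. For k-means the best of `n_init` restarts by within-cluster
#' sum of squared Euclidean distances is returned; spectral (k-nearest-
#' neighbour affinity graph, normalized Laplacian embedding) and
#' agglomerative (Euclidean distance, configurable linkage) clustering are
#' drop-in alternatives. Labels are renumbered to 1..k in order of first
#' appearance, so raw ids carry no meaning across subjects.
#'
#' @param cm a [connectivity_matrix()] (or plain matrix).
#' @param params a [cluster_params()].
#' @param subject_id subject identifier stored in the result.
#' @return A [labeling()].
#' @export
cluster_subject <- function(cm, params, subject_id = "") {
  X <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  if (!all(is.finite(X))) stop("connectivity matrix contains non-finite values")
  if (nrow(X) < params$k)
    stop("k = ", params$k, " exceeds the number of ROI voxels (", nrow(X), ")")
  if (nrow(unique(X)) < params$k)
    stop("k = ", params$k, " exceeds the number of distinct fingerprints")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(params$seed)
  labels <- switch(params$method,
                   kmeans = .cluster_kmeans(X, params),
                   agglomerative = .cluster_agglomerative(X, params),
                   spectral = .cluster_spectral(X, params))
  labels <- match(labels, unique(labels))   # canonical first-appearance ids
  labeling(labels, k = params$k, subject_id = subject_id, params = params)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Within-cluster sum of squares of a labeling
#'
#' The k-means objective: the sum over voxels of the squared Euclidean
#' distance to the centroid of the voxel's own cluster.
#'
#' @param cm a [connectivity_matrix()] (or plain matrix).
#' @param lab a [labeling()] or integer label vector.
#' @return Non-negative scalar.
#' @export
wss <- function(cm, lab) {
  X <- if (inherits(cm, "connectivity_matrix")) cm$values else as.matrix(cm)
  labels <- if (inherits(lab, "labeling")) lab$labels else as.integer(lab)
  if (length(labels) != nrow(X))
    stop("label count does not match matrix rows")
  total <- 0
  for (g in unique(labels)) {
    Xg <- X[labels == g, , drop = FALSE]
    ctr <- colMeans(Xg)
    total <- total + sum(sweep(Xg, 2, ctr)^2)
  }
  total
}
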