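# Validity indices and similarity metrics.

test_that("internal indices reproduce the hand-computed 1D example", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  l <- c(1, 1, 2, 2)
  expect_equal(silhouette_index(X, l), 0.8997494, tolerance = 1e-6)
  expect_equal(calinski_harabasz(X, l), 200)
  expect_equal(davies_bouldin(X, l), 0.1)
})

test_that("internal indices match brute-force oracles on random data", {
  set.seed(41)
  for (rep in 1:15) {
    n <- sample(20:60, 1)
    p <- sample(2:6, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    l <- random_labels(n, k, seed = 41 + rep)
    expect_equal(silhouette_index(X, l), oracle_silhouette(X, l),
                 tolerance = 1e-10)
    expect_equal(calinski_harabasz(X, l), oracle_ch(X, l), tolerance = 1e-9)
    expect_equal(davies_bouldin(X, l), oracle_db(X, l), tolerance = 1e-9)
  }
})

test_that("silhouette agrees with the cluster package cross-check", {
  skip_if_not_installed("cluster")
  set.seed(42)
  X <- matrix(rnorm(50 * 3), 50, 3)
  l <- random_labels(50, 3, seed = 7)
  sil <- cluster::silhouette(l, dist(X))
  expect_equal(silhouette_index(X, l), mean(sil[, "sil_width"]),
               tolerance = 1e-10)
})

test_that("degenerate index inputs give sentinels with warnings", {
  # zero within-cluster dispersion
  X <- matrix(rep(c(0, 10), each = 3), ncol = 1)
  expect_warning(ch <- calinski_harabasz(X, rep(1:2, each = 3)), "sentinel")
  expect_equal(ch, .Machine$double.xmax)
  # separated zero-spread clusters: perfect DB of 0
  expect_equal(davies_bouldin(X, rep(1:2, each = 3)), 0)
  # coincident centroids
  X2 <- matrix(c(-1, 1, -1, 1), ncol = 1)
  expect_warning(db <- davies_bouldin(X2, c(1, 1, 2, 2)), "sentinel")
  expect_equal(db, .Machine$double.xmax)
  expect_error(silhouette_index(X, rep(1, 6)), "2 <= k")
  expect_error(silhouette_index(X, 1:6), "2 <= k")
})

test_that("ARI matches its contingency-table definition and mclust", {
  expect_equal(ari(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)   # permutation
  skip_if_not_installed("mclust")
  set.seed(43)
  for (rep in 1:20) {
    a <- random_labels(40, 3, seed = 2000 + rep)
    b <- random_labels(40, 4, seed = 3000 + rep)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("V-measure and AMI behave at the boundaries", {
  a <- c(1, 1, 2, 2, 3)
  expect_equal(v_measure(a, a), 1)
  expect_equal(ami(a, a), 1)
  expect_equal(ami(a, c(3, 3, 1, 1, 2)), 1)       # identical up to renaming
  expect_equal(v_measure(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
  expect_error(ami(1:3, 1:4), "length")
  expect_error(v_measure(1:3, 1:4), "length")
})

test_that("AMI is approximately centred at zero for independent labelings", {
  set.seed(44)
  vals <- replicate(100, {
    a <- sample.int(3, 200, replace = TRUE)
    b <- sample.int(3, 200, replace = TRUE)
    ami(a, b)
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("similarity metrics are symmetric and permutation invariant", {
  set.seed(45)
  for (rep in 1:25) {
    a <- random_labels(30, 3, seed = 7000 + rep)
    b <- random_labels(30, 3, seed = 8000 + rep)
    perm <- sample(3)
    for (f in list(ari, v_measure, ami)) {
      expect_equal(f(a, b), f(b, a), tolerance = 1e-12)
      expect_equal(f(perm[a], b), f(a, b), tolerance = 1e-12)
    }
  }
})

test_that("indices rank the planted k best on separable synthetic parcels", {
  d <- planted_design(roi_shape = c(6L, 5L, 3L), k_true = 3L,
                      n_subjects = 1L, n_targets = 60L,
                      prototype_separation = 10, subject_noise_sd = 1,
                      seed = 46)
  co <- make_connectivity_cohort(d)
  cm <- co$matrices[[1]]
  scores <- lapply(2:5, function(k) {
    lab <- cluster_subject(cm, cluster_params(k = k, n_init = 10,
                                              max_iter = 200, seed = 10 + k))
    c(sil = silhouette_index(cm, lab), ch = calinski_harabasz(cm, lab),
      db = davies_bouldin(cm, lab))
  })
  sil <- vapply(scores, `[[`, numeric(1), "sil")
  ch <- vapply(scores, `[[`, numeric(1), "ch")
  db <- vapply(scores, `[[`, numeric(1), "db")
  expect_equal(which.max(sil), 2L)   # k = 3 is the 2nd entry of 2:5
  expect_equal(which.max(ch), 2L)
  expect_equal(which.min(db), 2L)
})

test_that("similarity_report builds pairwise, group and dendrogram views", {
  l <- labeling(rep(1:2, each = 5), k = 2, subject_id = "A")
  same <- labeling(rep(2:1, each = 5), k = 2, subject_id = "B")
  rep_id <- similarity_report(list(l, same), group = l$labels)
  expect_equal(unname(rep_id$pairwise["A", "B"]), 1)
  expect_equal(unname(rep_id$to_group), c(1, 1))
  expect_match(rep_id$caveat, "not independent")

  # two blocks of subjects with distinct labelings separate at the top split
  blockA <- lapply(1:3, function(i)
    labeling(rep(1:2, each = 5), k = 2, subject_id = paste0("A", i)))
  blockB <- lapply(1:3, function(i)
    labeling(rep(1:2, times = 5), k = 2, subject_id = paste0("B", i)))
  rep2 <- similarity_report(c(blockA, blockB), group = blockA[[1]]$labels)
  top <- cutree(rep2$tree, k = 2)
  expect_equal(length(unique(top[1:3])), 1)
  expect_equal(length(unique(top[4:6])), 1)
  expect_false(top[1] == top[4])

  # metric switch changes the numbers unless labelings are identical
  repa <- similarity_report(c(blockA, blockB), blockA[[1]]$labels,
                            metric = "ami")
  expect_false(isTRUE(all.equal(repa$pairwise, rep2$pairwise)))

  f <- withr::local_tempfile(fileext = ".png")
  plot_similarity_dendrogram(rep2, f)
  expect_true(file.size(f) > 0)
})

test_that("compare_reference reports similarity and aligned mismatches", {
  g <- rep(1:2, each = 10)
  self <- compare_reference(g, g)
  expect_equal(self$similarity, 1)
  expect_equal(self$n_mismatch, 0)

  refp <- c(2L, 1L)[g]                 # permuted ids only
  perm <- compare_reference(g, refp)
  expect_equal(perm$similarity, 1)
  expect_equal(perm$n_mismatch, 0)     # counted after optimal alignment

  ref <- g; ref[1:3] <- 3L - ref[1:3]
  cmp <- compare_reference(g, ref)
  expect_equal(cmp$n_mismatch, 3)
  expect_equal(cmp$pct_mismatch, 15)
  expect_lt(cmp$similarity, 1)
  expect_error(compare_reference(g, ref[1:5]), "voxel counts")
})
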