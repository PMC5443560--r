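test_that("argmax clustering resolves ties and empty columns as documented", {
  H <- cbind(c(0.1, 0.9), c(0.5, 0.5), c(0, 0), c(0.7, 0.3))
  asg <- assign_clusters(H)
  expect_equal(asg$cluster, c(2L, 1L, 1L, 1L))
  expect_equal(asg$tie, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(asg$empty, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(assign_clusters(cbind(c(-0.1, 1))), "non-negative")
})

test_that("argmax clustering agrees with per-column enumeration on random instances", {
  set.seed(1500)
  for (i in 1:25) {
    s <- sample(2:4, 1); n <- sample(2:8, 1)
    H <- matrix(round(stats::runif(s * n), 2), s, n)
    asg <- assign_clusters(H)
    for (v in seq_len(n)) {
      best <- which(H[, v] == max(H[, v]))
      expect_equal(asg$cluster[v], best[1L])
      expect_equal(asg$tie[v], length(best) > 1L && any(H[, v] > 0))
    }
  }
})

test_that("peak sorting groups columns by argmax row, descending peak within group", {
  H1 <- matrix(c(1, 0, 0, 2), 2, 2)
  expect_equal(sort_weights_by_peak(H1)$order, c(1L, 2L))

  H2 <- cbind(c(0.9, 0.1), c(0.2, 0.8), c(0.7, 0.3))
  sw <- sort_weights_by_peak(H2)
  expect_equal(sw$order, c(1L, 3L, 2L))
  expect_identical(sw$H_sorted, H2[, c(1, 3, 2)])

  # idempotence: re-sorting an already sorted matrix is the identity
  sw2 <- sort_weights_by_peak(sw$H_sorted)
  expect_equal(sw2$order, seq_len(3L))

  # random instances: returned order always satisfies the sort rule
  set.seed(1600)
  for (i in 1:25) {
    s <- sample(2:3, 1); n <- sample(2:6, 1)
    H <- matrix(stats::runif(s * n), s, n)
    expect_true(bf_valid_peak_order(H, sort_weights_by_peak(H)$order))
  }
})

test_that("block profiles average member columns and peak on their own dimension", {
  H <- cbind(c(1, 0), c(0.5, 0.5), c(0.2, 0.8))
  asg <- assign_clusters(H)
  bp <- block_profiles(H, asg)
  expect_equal(unname(bp[, 1]), c(0.75, 0.25))  # columns 1 and 2 (tie -> cluster 1)
  expect_equal(unname(bp[, 2]), c(0.2, 0.8))    # single-voxel cluster: its own column

  expect_error(block_profiles(H, asg, clusters = 3), "no member")

  # strongly block-diagonal planted weights: each mean vector peaks on itself
  p <- synthetic_atlas_params(grid_shape = c(6, 6, 2), n_regions = 3,
                              n_signature_genes_per_region = 5,
                              n_background_genes = 10, seed = 12)
  sim <- generate_atlas(p)
  fit <- als_nmf(sim$atlas$matrix, 3, max_iter = 200, tol = 1e-6, restarts = 3,
                 seed = 6)
  bp2 <- block_profiles(fit$H)
  expect_equal(unname(apply(bp2, 2, which.max)), 1:3)
})

test_that("basis dendrograms reproduce hand-computed distances and first merges", {
  # identical basis vectors merge at height 0
  W <- cbind(c(1, 2), c(1, 2), c(5, 9))
  hc <- basis_dendrogram(W)
  expect_equal(hc$height[1], 0)

  # 3-4-5 triangle distance
  expect_equal(unname(as.matrix(stats::dist(t(cbind(c(0, 0), c(3, 4)))))[1, 2]), 5)
  hc2 <- basis_dendrogram(cbind(c(0, 0), c(3, 4)))
  expect_equal(hc2$height, 5)

  # one close pair among mutually distant vectors: first merge joins it
  W3 <- cbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  hc3 <- basis_dendrogram(W3)
  expect_equal(hc3$height[1], 1)
  expect_equal(sort(-hc3$merge[1, ]), c(1, 2))

  expect_error(basis_dendrogram(matrix(1, 3, 1)), "at least 2")

  # random instances: first merge pair and height match brute force
  set.seed(1700)
  for (i in 1:20) {
    s <- sample(3:4, 1)
    W <- matrix(stats::runif(5 * s), 5, s)
    hc <- basis_dendrogram(W)
    bf <- bf_first_merge(W)
    expect_equal(sort(-hc$merge[1, ]), sort(bf$pair))
    expect_equal(hc$height[1], bf$height)
  }
})

test_that("permutation-matched accuracy is exact and relabeling-invariant", {
  # relabeled copy of the truth scores accuracy 1
  truth <- c(1L, 1L, 2L, 2L, 3L)
  swapped <- c(3L, 3L, 1L, 1L, 2L)
  expect_equal(classification_accuracy(swapped, truth, s = 3)$accuracy, 1)

  # 2 equal classes: any clustering scores at least 0.5 after matching
  set.seed(1800)
  truth2 <- rep(1:2, each = 10)
  for (i in 1:10) {
    rnd <- sample(1:2, 20, replace = TRUE)
    expect_gte(classification_accuracy(rnd, truth2, s = 2)$accuracy, 0.5)
  }

  # exhaustive agreement with brute-force enumeration, s <= 4
  for (i in 1:25) {
    s <- sample(2:4, 1); n <- sample(4:8, 1)
    pred <- sample(seq_len(s), n, replace = TRUE)
    truth3 <- sample(seq_len(s), n, replace = TRUE)
    res <- classification_accuracy(pred, truth3, s = s)
    expect_equal(res$accuracy, bf_accuracy(pred, truth3, s))
    # invariant under relabeling either side
    perm <- sample(seq_len(s))
    expect_equal(classification_accuracy(perm[pred], truth3, s = s)$accuracy,
                 res$accuracy)
    expect_equal(classification_accuracy(pred, perm[truth3], s = s)$accuracy,
                 res$accuracy)
  }
})

test_that("the accuracy curve saturates at the full gene set on noiseless planted data", {
  p <- synthetic_atlas_params(grid_shape = c(6, 6, 2), n_regions = 2,
                              n_signature_genes_per_region = 5,
                              n_background_genes = 15,
                              noise_dispersion = 0, seed = 41)
  sim <- generate_atlas(p)
  ac <- accuracy_vs_gene_count(sim$atlas, sim$truth$voxel_domain_labels,
                               gene_counts = c(25L), reps = 3, s = 2, seed = 14,
                               nmf_args = list(max_iter = 150, tol = 1e-7,
                                               restarts = 3))
  expect_equal(ac$mean_accuracy, 1)
  expect_equal(ac$perfect_fraction, 1)

  expect_error(accuracy_vs_gene_count(sim$atlas, sim$truth$voxel_domain_labels,
                                      gene_counts = 100L, reps = 2, s = 2),
               "exceeds")
  expect_error(accuracy_vs_gene_count(sim$atlas, sim$truth$voxel_domain_labels,
                                      gene_counts = 5L, reps = 0, s = 2),
               "reps")
})

test_that("planted parcellations are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  p <- synthetic_atlas_params(grid_shape = c(10, 10, 4), n_regions = 4,
                              n_signature_genes_per_region = 10,
                              n_background_genes = 60, seed = 77)
  sim <- generate_atlas(p)
  fit <- als_nmf(sim$atlas$matrix, 4, max_iter = 300, tol = 1e-5, restarts = 2,
                 seed = 19)
  asg <- assign_clusters(fit)
  ari <- mclust::adjustedRandIndex(asg$cluster, sim$truth$voxel_domain_labels)
  expect_gte(ari, 0.9)
})
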