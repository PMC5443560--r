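test_that("noiseless generation reproduces planted means exactly", {
  p <- synthetic_atlas_params(grid_shape = c(6, 6, 1), n_regions = 2,
                              n_signature_genes_per_region = 3,
                              n_background_genes = 4,
                              signature_mean = 10, background_mean = 1,
                              noise_dispersion = 0, seed = 1)
  sim <- generate_atlas(p)
  A <- sim$atlas$matrix
  labels <- sim$truth$voxel_domain_labels
  for (r in 1:2) {
    sig <- sim$truth$signature_gene_map[[paste0("domain_", r)]]
    expect_equal(unname(A[sig, labels == r]),
                 matrix(10, length(sig), sum(labels == r)), tolerance = 1e-6)
    expect_equal(unname(A[sig, labels != r]),
                 matrix(1, length(sig), sum(labels != r)), tolerance = 1e-6)
  }
  bg <- grep("^bg_", rownames(A), value = TRUE)
  expect_true(all(A[bg, ] == 1))
})

test_that("generation is deterministic in the seed", {
  p <- synthetic_atlas_params(grid_shape = c(5, 4, 2), n_regions = 2,
                              n_signature_genes_per_region = 3,
                              n_background_genes = 10, seed = 99)
  s1 <- generate_atlas(p)
  s2 <- generate_atlas(p)
  expect_identical(s1$atlas$matrix, s2$atlas$matrix)
  expect_identical(s1$truth$voxel_domain_labels, s2$truth$voxel_domain_labels)
  p2 <- synthetic_atlas_params(grid_shape = c(5, 4, 2), n_regions = 2,
                               n_signature_genes_per_region = 3,
                               n_background_genes = 10, seed = 100)
  s3 <- generate_atlas(p2)
  expect_false(identical(s1$atlas$matrix, s3$atlas$matrix))
})

test_that("block domains partition a 6x6x1 grid into two connected 18-voxel halves", {
  p <- synthetic_atlas_params(grid_shape = c(6, 6, 1), n_regions = 2,
                              n_signature_genes_per_region = 2,
                              n_background_genes = 2, seed = 3)
  sim <- generate_atlas(p)
  counts <- table(sim$truth$voxel_domain_labels)
  expect_equal(unname(as.vector(counts)), c(18L, 18L))
  vol <- sim$truth$label_volume
  expect_true(bf_connected6(vol == 1))
  expect_true(bf_connected6(vol == 2))
  # the blocks split the first (longest) axis into 3+3 planes
  expect_setequal(unique(as.vector(vol[1:3, , ])), 1L)
  expect_setequal(unique(as.vector(vol[4:6, , ])), 2L)
})

test_that("planted domains are connected for both geometries and labels cover every voxel", {
  for (geom in c("blocks", "voronoi")) {
    p <- synthetic_atlas_params(grid_shape = c(7, 6, 3), n_regions = 4,
                                n_signature_genes_per_region = 2,
                                n_background_genes = 2,
                                domain_geometry = geom, seed = 17)
    sim <- generate_atlas(p)
    expect_true(all(sim$truth$voxel_domain_labels %in% 1:4))
    expect_length(sim$truth$voxel_domain_labels, 7 * 6 * 3)
    for (r in 1:4) {
      expect_true(bf_connected6(sim$truth$label_volume == r),
                  label = sprintf("%s domain %d connected", geom, r))
    }
  }
  # disjoint signature sets
  p <- synthetic_atlas_params(grid_shape = c(4, 4, 2), n_regions = 3,
                              n_signature_genes_per_region = 5,
                              n_background_genes = 2, seed = 2)
  sim <- generate_atlas(p)
  sig <- sim$truth$signature_gene_map
  expect_equal(length(unique(unlist(sig))), 15L)
})

test_that("all noise models generate non-negative values with means near the planted means", {
  for (model in c("gamma", "lognormal", "truncated-normal")) {
    p <- synthetic_atlas_params(grid_shape = c(10, 10, 2), n_regions = 2,
                                n_signature_genes_per_region = 5,
                                n_background_genes = 50,
                                noise_model = model, noise_dispersion = 0.5,
                                seed = 11)
    sim <- generate_atlas(p)
    A <- sim$atlas$matrix
    expect_true(all(A >= 0), label = paste(model, "non-negative"))
    labels <- sim$truth$voxel_domain_labels
    sig1 <- sim$truth$signature_gene_map$domain_1
    expect_equal(mean(A[sig1, labels == 1]), 10, tolerance = 0.15)
    bg <- grep("^bg_", rownames(A), value = TRUE)
    expect_equal(mean(A[bg, ]), 1, tolerance = 0.15)
  }
})

test_that("grids too small for the requested domains are rejected", {
  p <- synthetic_atlas_params(grid_shape = c(2, 1, 1), n_regions = 4,
                              n_signature_genes_per_region = 1,
                              n_background_genes = 1, seed = 1)
  expect_error(generate_atlas(p), "too small")
  expect_error(synthetic_atlas_params(grid_shape = c(1, 1, 1)), "at least 2 voxels")
  expect_error(synthetic_atlas_params(n_regions = 0), "counts")
  expect_error(synthetic_atlas_params(replicate_corr_range = c(0.5, 0.1)), "ordered")
  expect_error(synthetic_atlas_params(noise_dispersion = -1), ">= 0")
})

test_that("replicate pairs hit the requested correlation regime", {
  # perfect-replicate limit: noiseless pair is identical with r = 1
  p1 <- synthetic_atlas_params(grid_shape = c(4, 4, 2), n_regions = 2,
                               n_signature_genes_per_region = 3,
                               n_background_genes = 5,
                               noise_dispersion = 0,
                               replicate_corr_range = c(1, 1), seed = 5)
  rp <- generate_replicate_pair(p1)
  expect_identical(rp$a$matrix, rp$b$matrix)
  rc <- replicate_correlations(rp$a, rp$b)
  expect_true(all(rc$r[rc$reason == "ok"] == 1))
  expect_true(all(rp$true_correlation == 1))

  # independent-replicate limit: mean sample correlation near 0 over >= 100 genes
  p0 <- synthetic_atlas_params(grid_shape = c(6, 6, 3), n_regions = 2,
                               n_signature_genes_per_region = 5,
                               n_background_genes = 190,
                               replicate_corr_range = c(0, 0), seed = 4)
  rp0 <- generate_replicate_pair(p0)
  rc0 <- replicate_correlations(rp0$a, rp0$b)
  expect_gte(sum(!is.na(rc0$r)), 100)
  expect_lt(abs(mean(rc0$r, na.rm = TRUE)), 0.1)

  # target correlations track sample correlations across the range
  pr <- synthetic_atlas_params(grid_shape = c(6, 6, 3), n_regions = 2,
                               n_signature_genes_per_region = 5,
                               n_background_genes = 190,
                               replicate_corr_range = c(-1, 1), seed = 8)
  rpr <- generate_replicate_pair(pr)
  rcr <- replicate_correlations(rpr$a, rpr$b)
  keep <- !is.na(rcr$r)
  expect_gt(stats::cor(rpr$true_correlation[keep], rcr$r[keep]), 0.8)
})
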