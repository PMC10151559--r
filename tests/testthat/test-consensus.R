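test_that("identical well-separated profiles always co-cluster", {
  set.seed(1)
  base <- matrix(rnorm(5 * 6, sd = 0.2), 5, 6) +
    outer(rep(1, 5), c(0, 0, 5, 5, 10, 15))
  base[, 2] <- base[, 1]  # two identical samples
  dimnames(base) <- list(paste0("G", 1:5), paste0("S", 1:6))
  res <- run_consensus(base, k_range = 2:4, reps = 20, p_item = 0.8, seed = 1)
  for (K in 2:4) {
    M <- res$consensus[[as.character(K)]]
    expect_equal(M["S1", "S2"], 1)
  }
})

test_that("p_item = 1 gives a binary consensus matrix that matches exhaustive co-membership", {
  m <- tiny_expr(6, 8, seed = 5)
  res <- run_consensus(m, k_range = 2:5, reps = 5, p_item = 1, seed = 1)
  hc <- hclust(as.dist(1 - cor(m)), method = "average")
  for (K in 2:5) {
    M <- res$consensus[[as.character(K)]]
    expect_true(all(M %in% c(0, 1)))
    lab <- cutree(hc, k = K)
    oracle <- outer(lab, lab, "==") * 1
    dimnames(oracle) <- dimnames(M)
    expect_equal(M, oracle)
  }
})

test_that("two planted blobs yield a block-structured consensus matrix", {
  co <- generate_cohort(cohort_spec(n_samples = 60, k_true = 2,
                                    n_cluster_genes = 20,
                                    cluster_separation = 5, noise_sd = 0.5,
                                    n_signature_genes = 4, n_noise_genes = 4,
                                    mutation_burden_means = c(5, 5), seed = 0))
  res <- run_consensus(co$expression, genes = co$truth$cluster_genes,
                       k_range = 2:4, reps = 50, p_item = 0.8, seed = 0)
  M <- res$consensus[["2"]]
  lab <- co$truth$cluster_labels[rownames(M)]
  same <- outer(lab, lab, "==")
  ut <- upper.tri(M)
  expect_gte(min(M[ut & same]), 0.95)
  expect_lte(max(M[ut & !same]), 0.05)
})

test_that("consensus CDF area matches its closed forms and a direct integral", {
  M <- matrix(0.5, 6, 6); diag(M) <- 1
  expect_equal(consensus_cdf_area(M)$area, 0.5)

  # binary matrix with fraction q of ones: area = 1 - q
  set.seed(2)
  B <- matrix(0, 8, 8)
  B[upper.tri(B)] <- rbinom(28, 1, 0.4)
  B <- B + t(B); diag(B) <- 1
  q <- mean(B[upper.tri(B)])
  expect_equal(consensus_cdf_area(B)$area, 1 - q)

  # random matrix: area equals the direct integral 1 - mean(entries)
  R <- matrix(0, 10, 10)
  R[upper.tri(R)] <- runif(45)
  R <- R + t(R); diag(R) <- 1
  v <- R[upper.tri(R)]
  expect_equal(consensus_cdf_area(R)$area, 1 - mean(v), tolerance = 1e-9)
})

test_that("delta-area K selection follows the stated arithmetic", {
  sel <- select_k(c(0.5, 0.9, 0.92, 0.93), k_range = 2:5)
  expect_equal(sel$selected_k, 3L)
  expect_equal(unname(sel$delta_area[2]), 0.8)
  expect_equal(unname(sel$delta_area[3]), 0.02 / 0.9, tolerance = 1e-12)
  # nothing above threshold: fall back to the smallest candidate
  expect_equal(select_k(c(0.05, 0.051, 0.052), 2:4)$selected_k, 2L)
})

test_that("consensus matrices are invariant to sample order when p_item = 1", {
  m <- tiny_expr(6, 8, seed = 3)
  perm <- c(3, 1, 4, 2, 8, 7, 5, 6)
  r1 <- run_consensus(m, k_range = 2:3, reps = 3, p_item = 1, seed = 1)
  r2 <- run_consensus(m[, perm], k_range = 2:3, reps = 3, p_item = 1, seed = 1)
  ids <- colnames(m)
  for (K in 2:3) {
    expect_equal(r2$consensus[[as.character(K)]][ids, ids],
                 r1$consensus[[as.character(K)]])
  }
})

test_that("CDF area is non-decreasing in K on the same data", {
  co <- generate_cohort(cohort_spec(n_samples = 80, seed = 4,
                                    n_noise_genes = 10))
  res <- run_consensus(co$expression, genes = co$truth$cluster_genes,
                       k_range = 2:6, reps = 40, seed = 4)
  expect_true(all(diff(res$area) >= -1e-9))
})

test_that("PCA projection preserves 2-D geometry and separates planted clusters", {
  # full-rank 2-D data: projection reproduces pairwise distances
  set.seed(6)
  m <- rbind(G1 = rnorm(12), G2 = rnorm(12))
  colnames(m) <- paste0("S", 1:12)
  pr <- pca_projection(m)
  d_orig <- dist(scale(t(m)))  # genes centered/scaled as the projection does
  d_proj <- dist(pr[, c("PC1", "PC2")])
  expect_equal(as.vector(d_proj), as.vector(d_orig), tolerance = 1e-9)

  co <- generate_cohort(cohort_spec(n_samples = 90, cluster_separation = 4,
                                    n_noise_genes = 5, seed = 8))
  pr2 <- pca_projection(co$expression, genes = co$truth$cluster_genes,
                        labels = co$truth$cluster_labels)
  sil <- cluster::silhouette(as.integer(pr2$label),
                             dist(pr2[, c("PC1", "PC2")]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  # degenerate input: all samples identical -> all coordinates zero
  flat <- matrix(5, 3, 4, dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
  expect_warning(pr3 <- pca_projection(flat), "constant")
  expect_true(all(pr3$PC1 == 0) && all(pr3$PC2 == 0))
})
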