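# A deterministic mini-cohort with known prognosis ordering: cluster 1 has
# long survival, cluster 3 short, and three archetypal genes.
mini_sig_cohort <- function() {
  set.seed(10)
  n_per <- 12
  labels <- rep(1:3, each = n_per)
  ids <- sprintf("S%02d", seq_along(labels))
  names(labels) <- ids
  # gene UP increases with cluster index, DOWN decreases, FLAT constant
  expr <- rbind(
    UP = labels * 2 + rnorm(length(labels), 0, 0.1),
    DOWN = -labels * 2 + rnorm(length(labels), 0, 0.1),
    FLAT = rep(5, length(labels)),
    FILL = rnorm(length(labels), 6, 0.5))
  colnames(expr) <- ids
  clin <- data.frame(sample_id = ids,
                     OS_time = c(rexp(n_per, 1 / 80), rexp(n_per, 1 / 30),
                                 rexp(n_per, 1 / 8)),
                     OS_event = 1L, stringsAsFactors = FALSE)
  list(expr = expr, labels = labels, clinical = clin)
}

test_that("signature assignment follows prognosis-ordered rank correlation", {
  d <- mini_sig_cohort()
  expect_message(
    pair <- assign_signatures(d$expr, c("UP", "DOWN", "FLAT"), d$labels,
                              d$clinical, endpoint = "OS"),
    "zero rank correlation")
  # cluster 1 is best, 3 worst: ordinal rises with cluster index, so the
  # increasing gene lands in signature A (high in poor prognosis)
  expect_equal(pair$cluster_order, c(1, 2, 3))
  expect_equal(pair$signature_A, "UP")
  expect_equal(pair$signature_B, "DOWN")
  expect_error(assign_signatures(d$expr, "UP", rep(1, ncol(d$expr)),
                                 d$clinical), "at least 2 clusters")
})

test_that("identical signatures cancel and the PC1 sign convention holds", {
  m <- tiny_expr(8, 20, seed = 2)
  pair <- structure(list(signature_A = rownames(m)[1:4],
                         signature_B = rownames(m)[1:4]),
                    class = "signature_pair")
  expect_warning(fit <- fit_scores(m, pair), "identical")
  expect_true(all(abs(fit$table$mmp_score) < 1e-12))

  pair2 <- structure(list(signature_A = rownames(m)[1:4],
                          signature_B = rownames(m)[5:8]),
                     class = "signature_pair")
  fit2 <- fit_scores(m, pair2)
  for (sig in c("A", "B")) {
    mm <- fit2$model[[sig]]
    Z <- scale(t(m[mm$genes, ]), center = mm$center, scale = mm$scale)
    s <- fit2$table[[paste0("pc1_", sig)]]
    expect_gt(cor(s, rowMeans(Z)), 0)
  }
})

test_that("scores are invariant to gene order, sample order and global shifts", {
  m <- tiny_expr(10, 25, seed = 4)
  pair <- structure(list(signature_A = rownames(m)[1:5],
                         signature_B = rownames(m)[6:10]),
                    class = "signature_pair")
  ref <- fit_scores(m, pair)

  shuf_genes <- m[sample(nrow(m)), ]
  expect_equal(fit_scores(shuf_genes, pair)$table$mmp_score,
               ref$table$mmp_score)

  perm <- sample(ncol(m))
  fit_perm <- fit_scores(m[, perm], pair)
  expect_equal(fit_perm$table$mmp_score[match(ref$table$sample_id,
                                              fit_perm$table$sample_id)],
               ref$table$mmp_score, tolerance = 1e-9)

  expect_equal(fit_scores(m + 3, pair)$table$mmp_score, ref$table$mmp_score,
               tolerance = 1e-9)
})

test_that("median split follows the strict-majority rule and flags degeneracy", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  expect_warning(g <- median_split(c(2, 2, 2)), "identical")
  expect_true(all(g == "low"))
})

test_that("projection with frozen loadings is exact and honors the imputation rule", {
  co <- generate_cohort(cohort_spec(n_samples = 120, n_noise_genes = 10,
                                    seed = 5))
  pair <- structure(list(signature_A = co$truth$up_genes,
                         signature_B = co$truth$down_genes),
                    class = "signature_pair")
  fit <- fit_scores(co$expression, pair)

  proj <- project_scores(co$expression, fit)
  expect_equal(proj$table$mmp_score, fit$table$mmp_score, tolerance = 1e-12)

  # deleting one signature-A gene = zeroing its centered contribution
  drop_gene <- fit$model$A$genes[1]
  expr2 <- co$expression[setdiff(rownames(co$expression), drop_gene), ]
  proj2 <- project_scores(expr2, fit, min_overlap = 0.5)
  mA <- fit$model$A
  Z <- scale(t(co$expression[mA$genes, ]), center = mA$center,
             scale = mA$scale)
  Z[, drop_gene] <- 0
  manual_A <- drop(Z %*% mA$rotation)
  expect_equal(proj2$table$pc1_A, unname(manual_A), tolerance = 1e-12)

  # refusing projection when too many genes are missing
  few <- co$expression[c(fit$model$A$genes[1:3], fit$model$B$genes), ]
  expect_error(project_scores(few, fit), "overlap")
})

test_that("scores transfer to an independent cohort from the same population", {
  train <- generate_cohort(cohort_spec(n_samples = 200, seed = 6))
  test_co <- generate_cohort(cohort_spec(n_samples = 200, seed = 106))
  pair <- structure(list(signature_A = train$truth$up_genes,
                         signature_B = train$truth$down_genes),
                    class = "signature_pair")
  fit <- fit_scores(train$expression, pair)
  proj <- project_scores(test_co$expression, fit)
  f <- test_co$truth$latent_factor[proj$table$sample_id]
  wt <- wilcox.test(f[proj$table$group == "high"],
                    f[proj$table$group == "low"])
  expect_lt(wt$p.value, 0.01)
  expect_gt(mean(f[proj$table$group == "high"]),
            mean(f[proj$table$group == "low"]))
})

test_that("high-score groups carry the higher latent factor across seeds", {
  ok <- vapply(1:10, function(s) {
    co <- generate_cohort(cohort_spec(n_samples = 120, n_noise_genes = 10,
                                      seed = s))
    pair <- structure(list(signature_A = co$truth$up_genes,
                           signature_B = co$truth$down_genes),
                      class = "signature_pair")
    fit <- fit_scores(co$expression, pair)
    f <- co$truth$latent_factor[fit$table$sample_id]
    mean(f[fit$table$group == "high"]) > mean(f[fit$table$group == "low"])
  }, TRUE)
  expect_true(all(ok))
})

test_that("Boruta separates planted signal from noise and respects its stopping rules", {
  set.seed(1)
  n <- 200
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("F", 1:20)))
  y <- factor(ifelse(X[, 1] + X[, 2] - X[, 3] + rnorm(n, 0, 0.4) > 0,
                     "a", "b"))
  br <- boruta_select(X, y, max_iter = 60, alpha = 0.01, seed = 1,
                      num_trees = 300)
  expect_true(all(c("F1", "F2", "F3") %in% br$confirmed))
  expect_setequal(c(br$confirmed, br$rejected, br$tentative), colnames(X))

  # one iteration cannot reach binomial significance
  br1 <- boruta_select(X, y, max_iter = 1, seed = 1)
  expect_length(br1$tentative, 20)
  expect_length(br1$confirmed, 0)

  # determinism
  br2 <- boruta_select(X, y, max_iter = 10, seed = 7, num_trees = 200)
  br3 <- boruta_select(X, y, max_iter = 10, seed = 7, num_trees = 200)
  expect_identical(br2$hits, br3$hits)
})

test_that("Boruta confirms almost nothing when the target is shuffled", {
  n_confirmed <- vapply(0:4, function(s) {
    set.seed(s)
    X <- matrix(rnorm(400 * 50), 400, 50,
                dimnames = list(NULL, paste0("F", 1:50)))
    y <- factor(sample(rep(c("a", "b"), 200)))
    length(boruta_select(X, y, max_iter = 40, seed = s,
                         num_trees = 200)$confirmed)
  }, 0L)
  expect_lte(sum(n_confirmed), 2)
})

test_that("reduce_signatures drops unconfirmed genes but keeps the partition", {
  co <- generate_cohort(cohort_spec(n_samples = 150, n_noise_genes = 10,
                                    seed = 12))
  pair <- structure(list(signature_A = c(co$truth$up_genes,
                                         co$truth$cluster_genes[1:5]),
                         signature_B = co$truth$down_genes,
                         cluster_order = 1:3),
                    class = "signature_pair")
  red <- reduce_signatures(co$expression, pair, co$truth$cluster_labels,
                           max_iter = 20, num_trees = 150, seed = 2)
  expect_true(all(red$pair$signature_A %in% pair$signature_A))
  expect_true(all(red$pair$signature_B %in% pair$signature_B))
  expect_length(intersect(red$pair$signature_A, red$pair$signature_B), 0)
})
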