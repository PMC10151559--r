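test_that("rank tests reproduce exact and degenerate cases", {
  rt <- rank_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(rt$method, "wilcoxon-exact")
  expect_equal(rt$p, 0.1)

  same <- rank_test(rep(c(1, 2, 3), 3), rep(c("g1", "g2", "g3"), each = 3))
  expect_equal(same$method, "kruskal-wallis")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  expect_error(rank_test(1:4, rep("a", 4)), "at least 2")
})

test_that("rank tests are invariant to monotone transforms", {
  set.seed(1)
  v <- rnorm(40); g <- rep(c("a", "b"), 20)
  p1 <- rank_test(v, g)$p
  expect_equal(rank_test(exp(v), g)$p, p1, tolerance = 1e-12)
  expect_equal(rank_test(v^3, g)$p, p1, tolerance = 1e-12)
  k <- rep(c("a", "b", "c"), c(13, 13, 14))
  expect_equal(rank_test(plogis(v), k)$p, rank_test(v, k)$p,
               tolerance = 1e-12)
})

test_that("the k-sample rank test keeps its nominal type-I error", {
  set.seed(20)
  rej <- mean(vapply(1:500, function(i) {
    v <- rnorm(90)
    rank_test(v, rep(c("a", "b", "c"), each = 30))$p < 0.05
  }, TRUE))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("burden comparison detects planted Poisson shifts and rejects bad input", {
  set.seed(0)
  burden <- c(rpois(100, 8), rpois(100, 4))
  grp <- factor(rep(c("low", "high"), each = 100), levels = c("low", "high"))
  cmp <- mutation_burden_compare(burden, grp)
  expect_lt(cmp$p, 0.01)
  expect_gt(cmp$medians[["low"]], cmp$medians[["high"]])

  ident <- mutation_burden_compare(rep(c(1L, 2L, 3L), 2),
                                   rep(c("low", "high"), each = 3))
  expect_gt(ident$p, 0.99)

  expect_error(mutation_burden_compare(c(-1, 2, 3), c("a", "a", "b")),
               "non-negative")
  expect_error(mutation_burden_compare(c(1, 2, 3), c("a", "a", "a")),
               "at least 2")
})

test_that("per-gene logistic association reproduces the closed-form 2x2 odds ratio", {
  grp <- factor(rep(c("low", "high"), each = 100), levels = c("high", "low"))
  names(grp) <- sprintf("S%03d", 1:200)
  mat <- matrix(0L, 2, 200, dimnames = list(c("GA", "GB"), names(grp)))
  mat["GA", c(1:30, 101:110)] <- 1L   # 30/100 low, 10/100 high
  mat["GB", c(1:25, 101:125)] <- 1L   # equal rates
  res <- per_gene_mutation_assoc(mat, grp, min_mutated = 10)
  ga <- res[res$gene_id == "GA", ]
  expect_equal(ga$odds_ratio, 27 / 7, tolerance = 1e-9)
  expect_equal(ga$odds_ratio, exp(ga$beta), tolerance = 1e-9)
  expect_equal(ga$mut_low + ga$wt_low + ga$mut_high + ga$wt_high, 200)
  gb <- res[res$gene_id == "GB", ]
  expect_equal(gb$odds_ratio, 1, tolerance = 1e-9)
  expect_gt(gb$p, 0.9)

  # swapping group labels inverts the odds ratio
  swapped <- factor(ifelse(grp == "low", "high", "low"),
                    levels = c("high", "low"))
  names(swapped) <- names(grp)
  res2 <- per_gene_mutation_assoc(mat, swapped, min_mutated = 10)
  expect_equal(res2$odds_ratio[res2$gene_id == "GA"], 7 / 27,
               tolerance = 1e-9)
})

test_that("zero cells get the Haldane-Anscombe correction and a flag", {
  grp <- factor(rep(c("low", "high"), each = 30), levels = c("high", "low"))
  names(grp) <- sprintf("S%03d", 1:60)
  mat <- matrix(0L, 1, 60, dimnames = list("GZ", names(grp)))
  mat["GZ", 1:12] <- 1L  # all mutations in the low group
  res <- per_gene_mutation_assoc(mat, grp, min_mutated = 10)
  expect_true(res$flagged)
  expect_equal(res$beta,
               log((12.5 * 30.5) / (18.5 * 0.5)), tolerance = 1e-9)
})

test_that("Wald and Fisher decisions agree on well-filled 2x2 tables", {
  set.seed(7)
  agree <- 0; log_gap_ok <- 0; n_tab <- 0
  while (n_tab < 200) {
    p1 <- runif(1, 0.25, 0.75); p2 <- runif(1, 0.25, 0.75)
    m <- c(rbinom(1, 60, p1), rbinom(1, 60, p2))
    tab <- rbind(c(m[1], 60 - m[1]), c(m[2], 60 - m[2]))
    if (min(tab) < 5) next
    n_tab <- n_tab + 1
    grp <- factor(rep(c("low", "high"), each = 60), levels = c("high", "low"))
    names(grp) <- sprintf("S%03d", 1:120)
    mut <- matrix(0L, 1, 120, dimnames = list("G", names(grp)))
    mut["G", c(seq_len(m[1]), 60 + seq_len(m[2]))] <- 1L
    wald <- per_gene_mutation_assoc(mut, grp, min_mutated = 5)$p
    fis <- fisher.test(tab)$p.value
    agree <- agree + ((wald < 0.05) == (fis < 0.05))
    log_gap_ok <- log_gap_ok + (abs(log10(wald) - log10(fis)) <= 1)
  }
  expect_gte(agree / n_tab, 0.95)
  expect_gte(log_gap_ok / n_tab, 0.95)
})

test_that("clinicopathological associations pick up stage-linked scores", {
  co <- generate_cohort(cohort_spec(n_samples = 200, n_noise_genes = 5,
                                    seed = 3))
  stage_idx <- match(co$clinical$TNM, c("I", "II", "III", "IV"))
  set.seed(3)
  scores <- setNames(stage_idx + rnorm(200, 0, 0.3), co$clinical$sample_id)
  res <- clinicopath_association(scores, co$clinical)
  expect_lt(res$TNM$p, 0.001)

  single <- co$clinical
  single$M <- "M0"
  expect_warning(res2 <- clinicopath_association(scores, single),
                 "fewer than 2")
  expect_false("M" %in% names(res2))
})

test_that("significance stars follow the figure-legend convention", {
  expect_equal(p_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
               c("ns", "*", "**", "***", "****"))
})
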