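#' Rank-based group comparison
#'
#' Two groups: Wilcoxon rank-sum, exact when both groups have at most 10
#' observations and the data are tie-free, otherwise the normal
#' approximation with tie correction. Three or more groups:
#' Kruskal-Wallis H with tie correction and a chi-square p-value.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param mode `"auto"` (choose by group count), `"two-sample"`, or
#'   `"k-sample"`.
#' @param covariate optional name recorded in the result.
#' @return a `group_comparison` list: `covariate`, `method`, `statistic`,
#'   `p`, `n` (per group), `medians` (per group), `stars`.
#' @export
rank_test <- function(values, groups, mode = c("auto", "two-sample", "k-sample"),
                      covariate = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 non-empty groups")
  if (mode == "auto") mode <- if (k == 2) "two-sample" else "k-sample"
  if (mode == "two-sample" && k != 2) stop("two-sample mode needs exactly 2 groups")

  if (mode == "two-sample") {
    v1 <- values[groups == levels(groups)[1]]
    v2 <- values[groups == levels(groups)[2]]
    use_exact <- length(v1) <= 10 && length(v2) <= 10 &&
      !any(duplicated(c(v1, v2)))
    ht <- stats::wilcox.test(v1, v2, exact = use_exact, correct = !use_exact)
    method <- if (use_exact) "wilcoxon-exact" else "wilcoxon-normal"
  } else {
    ht <- stats::kruskal.test(values, groups)
    method <- "kruskal-wallis"
  }
  structure(list(covariate = covariate, method = method,
                 statistic = unname(ht$statistic), p = unname(ht$p.value),
                 n = table(groups),
                 medians = tapply(values, groups, stats::median),
                 stars = p_stars(unname(ht$p.value))),
            class = "group_comparison")
}

#' Compare mutation burden between score groups
#'
#' Two-sample rank test of the per-sample qualifying-variant counts between
#' the high and low score groups.
#'
#' @param burden named non-negative integer vector of per-sample variant
#'   counts.
#' @param score_groups per-sample group factor (`low`/`high`), named by
#'   sample if `burden` is named.
#' @return a `group_comparison` (see [rank_test()]).
#' @export
mutation_burden_compare <- function(burden, score_groups) {
  if (any(burden < 0) || any(burden != round(burden))) {
    stop("burden must be non-negative integers")
  }
  if (!is.null(names(burden)) && !is.null(names(score_groups))) {
    common <- intersect(names(burden), names(score_groups))
    burden <- burden[common]
    score_groups <- score_groups[common]
  }
  rank_test(as.numeric(burden), score_groups, mode = "two-sample",
            covariate = "mutation_burden")
}

#' Per-gene mutation association with score group
#'
#' For every gene mutated in at least `min_mutated` samples, fits a
#' logistic regression (IRLS via [stats::glm()]) of mutation status on the
#' score group with the HIGH group as reference, so an odds ratio above 1
#' means the gene is mutated more often in the LOW-score group. If the 2x2
#' table has a zero cell the Haldane-Anscombe 0.5 correction is applied in
#' closed form and the row is flagged. Wald p-values are BH-adjusted across
#' the tested genes.
#'
#' @param mutations binary gene x sample matrix (or the list returned by
#'   [mutation_matrix_from_maf()]).
#' @param score_groups per-sample factor (`low`/`high`), named by sample ID.
#' @param min_mutated minimum mutated samples for a gene to be tested
#'   (default 10).
#' @return data.frame per tested gene: `gene_id`, `odds_ratio`, `beta`,
#'   `se`, `p`, `q`, the 2x2 counts (`mut_low`, `wt_low`, `mut_high`,
#'   `wt_high`) and `flagged`.
#' @export
per_gene_mutation_assoc <- function(mutations, score_groups, min_mutated = 10) {
  mat <- if (is.list(mutations) && !is.null(mutations$matrix)) {
    mutations$matrix
  } else mutations
  stopifnot(all(mat %in% c(0, 1)))
  common <- intersect(colnames(mat), names(score_groups))
  if (length(common) == 0) stop("no samples shared between mutations and groups")
  mat <- mat[, common, drop = FALSE]
  grp <- factor(score_groups[common], levels = c("high", "low"))
  if (any(is.na(grp))) stop("score_groups must be 'low'/'high'")

  test_genes <- rownames(mat)[rowSums(mat) >= min_mutated]
  rows <- lapply(test_genes, function(g) {
    m <- mat[g, ]
    a <- sum(m == 1 & grp == "low");  b <- sum(m == 0 & grp == "low")
    c_ <- sum(m == 1 & grp == "high"); d <- sum(m == 0 & grp == "high")
    if (min(a, b, c_, d) == 0) {
      beta <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)))
      se <- sqrt(1 / (a + 0.5) + 1 / (b + 0.5) + 1 / (c_ + 0.5) + 1 / (d + 0.5))
      flagged <- TRUE
    } else {
      fit <- stats::glm(m ~ grp, family = stats::binomial(),
                        control = list(epsilon = 1e-12, maxit = 100))
      beta <- unname(stats::coef(fit)["grplow"])
      se <- unname(sqrt(diag(stats::vcov(fit)))["grplow"])
      flagged <- FALSE
    }
    data.frame(gene_id = g, odds_ratio = exp(beta), beta = beta, se = se,
               p = 2 * stats::pnorm(-abs(beta / se)),
               mut_low = a, wt_low = b, mut_high = c_, wt_high = d,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(0), odds_ratio = numeric(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0),
                      q = numeric(0), mut_low = integer(0), wt_low = integer(0),
                      mut_high = integer(0), wt_high = integer(0),
                      flagged = logical(0)))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), c("gene_id", "odds_ratio", "beta", "se", "p", "q",
                      "mut_low", "wt_low", "mut_high", "wt_high", "flagged")]
}

#' Score vs clinicopathological covariates
#'
#' k-sample rank test of the per-sample score across the levels of each
#' ordinal covariate (T/N/M/G/TNM stage by default). Covariates with fewer
#' than two non-empty levels are skipped with a warning.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param clinical clinical data.frame with a `sample_id` column.
#' @param covariates covariate column names to test.
#' @return list of `group_comparison` results, named by covariate.
#' @export
clinicopath_association <- function(scores, clinical,
                                    covariates = c("T", "N", "M", "G", "TNM")) {
  stopifnot(!is.null(names(scores)))
  clinical <- clinical[clinical$sample_id %in% names(scores), , drop = FALSE]
  s <- scores[clinical$sample_id]
  covariates <- intersect(covariates, colnames(clinical))
  out <- list()
  for (cv in covariates) {
    levs <- unique(stats::na.omit(clinical[[cv]]))
    if (length(levs) < 2) {
      warning("covariate ", cv, " has fewer than 2 levels; skipped")
      next
    }
    out[[cv]] <- rank_test(s, clinical[[cv]], mode = "auto", covariate = cv)
  }
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4g, p = %.4g %s\n",
              if (is.na(x$covariate)) "comparison" else x$covariate,
              x$method, x$statistic, x$p, x$stars))
  invisible(x)
}
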