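#' Assign DEGs to prognosis-oriented signatures A and B
#'
#' Orders the consensus clusters by prognosis — best first — using the
#' within-cluster Kaplan-Meier survival probability evaluated at the largest
#' follow-up time common to all clusters, so the ordinal cluster variable
#' increases as prognosis worsens. Each DEG's Spearman correlation with that
#' ordinal is computed across samples: positive correlation (higher
#' expression in poorer-prognosis clusters) assigns the gene to signature A,
#' negative to signature B, and exactly-zero correlations are excluded with
#' a message. With this orientation a high signature-A / low signature-B
#' profile — hence a high PC1-difference score — marks poor prognosis, so
#' the final score reads "low score, better outcome".
#'
#' @param expr expression matrix, genes x samples.
#' @param deg_genes character vector of DEG IDs (from [filter_degs()]).
#' @param labels per-sample cluster labels.
#' @param clinical clinical table with the chosen endpoint.
#' @param endpoint endpoint name used for prognosis ordering (default "OS").
#' @return a `signature_pair` list: `signature_A`, `signature_B`,
#'   `cluster_order` (best to worst), `correlations` (per-gene Spearman r).
#' @export
assign_signatures <- function(expr, deg_genes, labels, clinical,
                              endpoint = "OS") {
  validate_expression_matrix(expr)
  labels <- align_labels(labels, colnames(expr))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  deg_genes <- intersect(deg_genes, rownames(expr))
  if (length(deg_genes) == 0) stop("no DEG is present in the expression matrix")

  surv <- endpoint_subset(clinical, endpoint)
  surv <- surv[surv$sample_id %in% colnames(expr), , drop = FALSE]
  if (nrow(surv) == 0) stop("no overlap between expression and clinical samples")
  surv$cluster <- labels[surv$sample_id]

  # KM survival at the largest common follow-up time; higher = better
  tau <- min(tapply(surv$time, surv$cluster, max))
  s_at_tau <- vapply(clusters, function(cl) {
    d <- surv[surv$cluster == cl, ]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    summary(fit, times = tau, extend = TRUE)$surv
  }, 0)
  cluster_order <- clusters[order(s_at_tau, decreasing = TRUE)]  # best first
  ordinal <- match(labels, cluster_order)  # increases as prognosis worsens

  rs <- apply(expr[deg_genes, , drop = FALSE], 1, function(g) {
    suppressWarnings(stats::cor(g, ordinal, method = "spearman"))
  })
  rs[is.na(rs)] <- 0
  if (any(rs == 0)) {
    message("assign_signatures: excluding ", sum(rs == 0),
            " gene(s) with zero rank correlation")
  }
  structure(list(signature_A = deg_genes[rs > 0],
                 signature_B = deg_genes[rs < 0],
                 cluster_order = cluster_order,
                 correlations = rs),
            class = "signature_pair")
}

#' Fit the PC1-difference score on a training cohort
#'
#' For each signature: center and unit-variance scale its genes across
#' samples, take the first principal component over samples, and orient PC1
#' so it correlates positively with the mean scaled expression of that
#' signature's genes (the sign convention that makes the score direction
#' reproducible). The per-sample score is `PC1A - PC1B`, and samples are
#' split at the median score (strictly above the median = "high"). Gene
#' means, scales and oriented loadings are frozen in the returned model so
#' external cohorts can be projected without refitting.
#'
#' Constant genes carry no information and are dropped with a warning; a
#' signature whose genes are all constant is an error.
#'
#' @param expr expression matrix, genes x samples.
#' @param pair a `signature_pair` (typically after Boruta reduction via
#'   [reduce_signatures()]).
#' @return a `score_fit` list: `table` (data.frame `sample_id`, `pc1_A`,
#'   `pc1_B`, `mmp_score`, `group`) and `model` (frozen per-signature
#'   `genes`, `center`, `scale`, `rotation`).
#' @export
fit_scores <- function(expr, pair) {
  validate_expression_matrix(expr)
  fitted <- lapply(c(A = "signature_A", B = "signature_B"), function(slot) {
    genes <- intersect(pair[[slot]], rownames(expr))
    if (length(genes) == 0) stop("empty signature: ", slot)
    Xs <- t(expr[genes, , drop = FALSE])
    sds <- apply(Xs, 2, stats::sd)
    if (all(sds == 0)) stop("signature ", slot, " has only constant genes")
    if (any(sds == 0)) {
      warning("dropping ", sum(sds == 0), " constant gene(s) from ", slot)
      Xs <- Xs[, sds > 0, drop = FALSE]
      genes <- colnames(Xs)
      sds <- sds[sds > 0]
    }
    ctr <- colMeans(Xs)
    Z <- scale(Xs, center = ctr, scale = sds)
    w <- stats::prcomp(Z, center = FALSE, scale. = FALSE)$rotation[, 1]
    s <- drop(Z %*% w)
    # sign convention: PC1 tracks the signature's mean expression
    if (stats::cor(s, rowMeans(Z)) < 0) {
      w <- -w
      s <- -s
    }
    list(genes = genes, center = ctr, scale = sds, rotation = w, scores = s)
  })
  score <- fitted$A$scores - fitted$B$scores
  tab <- data.frame(sample_id = colnames(expr),
                    pc1_A = fitted$A$scores, pc1_B = fitted$B$scores,
                    mmp_score = score,
                    group = median_split(score),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab,
                 model = lapply(fitted, function(f) f[c("genes", "center",
                                                        "scale", "rotation")])),
            class = "score_fit")
}

#' Median dichotomization of a score vector
#'
#' Scores strictly above the median are "high", the rest "low". If every
#' score is identical the split is degenerate: all samples are "low" and a
#' warning is emitted.
#'
#' @param scores numeric vector (length >= 2).
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 2)
  med <- stats::median(scores)
  if (all(scores == scores[1])) {
    warning("all scores identical; degenerate median split (all low)")
  }
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Reduce signatures to the Boruta-confirmed genes
#'
#' Runs [boruta_select()] jointly on the pooled signature A and B genes with
#' the cluster labels as classification target, and drops unconfirmed genes
#' (tentative features are excluded from scoring by default).
#'
#' @param expr expression matrix, genes x samples.
#' @param pair a `signature_pair`.
#' @param labels per-sample cluster labels (the Boruta target).
#' @param ... passed to [boruta_select()] (`max_iter`, `alpha`, `seed`,
#'   `num_trees`).
#' @param keep_tentative if `TRUE`, tentative genes are retained.
#' @return `list(pair = reduced signature_pair, boruta = boruta_result)`.
#' @export
reduce_signatures <- function(expr, pair, labels, ..., keep_tentative = FALSE) {
  genes <- intersect(c(pair$signature_A, pair$signature_B), rownames(expr))
  labels <- align_labels(labels, colnames(expr))
  br <- boruta_select(t(expr[genes, , drop = FALSE]), labels, ...)
  kept <- br$confirmed
  if (keep_tentative) kept <- c(kept, br$tentative)
  reduced <- structure(list(signature_A = intersect(pair$signature_A, kept),
                            signature_B = intersect(pair$signature_B, kept),
                            cluster_order = pair$cluster_order,
                            correlations = pair$correlations),
                       class = "signature_pair")
  list(pair = reduced, boruta = br)
}

#' Project frozen signature scores onto a new cohort
#'
#' Scores new samples with the loadings, gene means and scales frozen at
#' training time — no refitting. Signature genes absent from the new cohort
#' are imputed at the frozen training mean, i.e. they contribute 0 after
#' centering; if the fraction of available genes falls below `min_overlap`
#' for either signature, the projection is refused and the missing genes are
#' listed. The high/low split is recomputed at the new cohort's own median.
#'
#' @param new_expr expression matrix of the new cohort, genes x samples.
#' @param fit a `score_fit` from [fit_scores()].
#' @param min_overlap minimum fraction of signature genes that must be
#'   present (default 0.7).
#' @return a `score_fit` for the new cohort (same frozen `model`).
#' @export
project_scores <- function(new_expr, fit, min_overlap = 0.7) {
  validate_expression_matrix(new_expr)
  stopifnot(inherits(fit, "score_fit"))
  scores <- lapply(fit$model, function(m) {
    present <- intersect(m$genes, rownames(new_expr))
    frac <- length(present) / length(m$genes)
    if (frac < min_overlap) {
      stop("signature gene overlap ", sprintf("%.0f%%", 100 * frac),
           " below threshold; missing: ",
           paste(setdiff(m$genes, present), collapse = ", "))
    }
    Z <- matrix(0, nrow = ncol(new_expr), ncol = length(m$genes),
                dimnames = list(colnames(new_expr), m$genes))
    Z[, present] <- scale(t(new_expr[present, , drop = FALSE]),
                          center = m$center[present],
                          scale = m$scale[present])
    drop(Z %*% m$rotation)
  })
  score <- scores$A - scores$B
  tab <- data.frame(sample_id = colnames(new_expr),
                    pc1_A = scores$A, pc1_B = scores$B,
                    mmp_score = score, group = median_split(score),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, model = fit$model), class = "score_fit")
}

#' @export
print.score_fit <- function(x, ...) {
  cat("PC1-difference score over", length(x$model$A$genes), "A +",
      length(x$model$B$genes), "B genes;",
      nrow(x$table), "samples (",
      sum(x$table$group == "high"), "high /",
      sum(x$table$group == "low"), "low )\n")
  invisible(x)
}
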