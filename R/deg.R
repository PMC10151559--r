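#' Moderated one-vs-rest differential expression between clusters
#'
#' For every gene and every cluster-vs-rest contrast, computes the log2 fold
#' change as the difference of group means (the input is already on the log2
#' scale), a t statistic whose gene-wise variance is shrunk toward a pooled
#' prior by the standard empirical-Bayes moments estimator
#' ([limma::squeezeVar()]), a two-sided p-value on the augmented degrees of
#' freedom, and a Benjamini-Hochberg adjusted p across all gene x contrast
#' tests jointly.
#'
#' `prior_df` overrides the estimated prior degrees of freedom; `prior_df =
#' 0` disables shrinkage entirely, recovering the ordinary pooled-variance
#' two-sample t statistic.
#'
#' @param expr expression matrix, genes x samples (log2 scale).
#' @param labels per-sample cluster labels (named or in column order).
#' @param prior_df `NULL` (estimate via the moments method) or a
#'   non-negative number; 0 = plain pooled t.
#' @param p_threshold adjusted-p cutoff recorded in the `passes` flag
#'   (default 0.05).
#' @param lfc_threshold absolute log2-fold-change cutoff for `passes`
#'   (default 1).
#' @return data.frame with one row per gene x contrast: `gene_id`,
#'   `contrast`, `log2fc`, `t`, `df_total`, `p`, `p_adj`, `passes`.
#' @export
moderated_deg_table <- function(expr, labels, prior_df = NULL,
                                p_threshold = 0.05, lfc_threshold = 1) {
  validate_expression_matrix(expr)
  labels <- align_labels(labels, colnames(expr))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  sizes <- table(labels)
  if (any(sizes < 2)) {
    stop("cluster(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }

  res <- lapply(clusters, function(cl) {
    idx <- labels == cl
    n1 <- sum(idx); n0 <- sum(!idx)
    m1 <- rowMeans(expr[, idx, drop = FALSE])
    m0 <- rowMeans(expr[, !idx, drop = FALSE])
    v1 <- apply(expr[, idx, drop = FALSE], 1, stats::var)
    v0 <- apply(expr[, !idx, drop = FALSE], 1, stats::var)
    df <- n1 + n0 - 2
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
    lfc <- m1 - m0

    if (is.null(prior_df)) {
      sq <- limma::squeezeVar(s2, df)
      s2_post <- sq$var.post
      d0 <- sq$df.prior
    } else if (prior_df == 0) {
      s2_post <- s2
      d0 <- 0
    } else {
      sq <- limma::squeezeVar(s2, df)
      s2_post <- (prior_df * sq$var.prior + df * s2) / (prior_df + df)
      d0 <- prior_df
    }
    se <- sqrt(s2_post * (1 / n1 + 1 / n0))
    tt <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
    df_total <- df + ifelse(is.finite(d0), d0, Inf)
    p <- 2 * stats::pt(-abs(tt), df = df_total)
    p[se == 0 & lfc == 0] <- 1  # no signal, no variance
    data.frame(gene_id = rownames(expr),
               contrast = paste0("cluster", cl, "_vs_rest"),
               log2fc = lfc, t = tt, df_total = df_total, p = p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab$passes <- tab$p_adj < p_threshold & abs(tab$log2fc) > lfc_threshold
  tab
}

#' Filter a DEG table to the union of passing genes
#'
#' A gene qualifies if it passes the thresholds in at least one
#' cluster-vs-rest contrast (union rule). Thresholds default to the
#' conventional adjusted p < 0.05 and |log2FC| > 1 and are applied to the
#' stored `p_adj` and `log2fc` columns, so they can be varied without
#' recomputing the table.
#'
#' @param records data.frame from [moderated_deg_table()].
#' @param p_threshold adjusted-p cutoff.
#' @param lfc_threshold absolute log2FC cutoff.
#' @return character vector of gene IDs (possibly empty).
#' @export
filter_degs <- function(records, p_threshold = 0.05, lfc_threshold = 1) {
  if (is.null(records) || nrow(records) == 0) return(character(0))
  pass <- records$p_adj < p_threshold & abs(records$log2fc) > lfc_threshold
  unique(records$gene_id[pass])
}

# Match a label vector to sample IDs: if named, reorder by name; otherwise
# require positional agreement.
align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    if (!all(sample_ids %in% names(labels))) {
      stop("labels are missing for some samples")
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("labels length does not match number of samples")
  }
  stats::setNames(as.vector(labels), sample_ids)
}
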