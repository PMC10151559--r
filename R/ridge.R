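#' Ridge-regression drug-sensitivity imputation
#'
#' Given a reference drug panel (baseline expression plus measured log-IC50
#' per cell line), fits an intercept-plus-ridge model on the genes shared
#' between the reference and the target cohort — standardized on the
#' reference statistics — and predicts per-sample log-IC50 for the cohort.
#' The penalty is either supplied directly or selected by 5-fold
#' cross-validation over a log-spaced grid (`lambda = "cv"`). Shared-gene
#' coverage below `min_overlap` of the reference genes is refused.
#'
#' The ridge solution is computed from the singular value decomposition of
#' the standardized reference matrix, so `lambda = 0` is the least-squares
#' limit and very large penalties shrink every prediction to the training
#' mean log-IC50.
#'
#' @param reference_expr reference expression, genes x cell lines.
#' @param reference_log_ic50 measured log-IC50 per cell line.
#' @param cohort_expr target cohort expression, genes x samples.
#' @param lambda non-negative penalty, or `"cv"` (default) for 5-fold CV.
#' @param min_overlap minimum shared fraction of reference genes (default
#'   0.5).
#' @param n_folds CV folds (default 5).
#' @param seed RNG seed for the CV fold assignment.
#' @return named numeric vector of predicted log-IC50 per cohort sample,
#'   with attributes `lambda` (the penalty used) and `n_genes`.
#' @export
ridge_drug_response <- function(reference_expr, reference_log_ic50,
                                cohort_expr, lambda = "cv",
                                min_overlap = 0.5, n_folds = 5, seed = 1L) {
  stopifnot(is.matrix(reference_expr), is.matrix(cohort_expr))
  y <- as.numeric(reference_log_ic50)
  stopifnot(length(y) == ncol(reference_expr))
  shared <- intersect(rownames(reference_expr), rownames(cohort_expr))
  frac <- length(shared) / nrow(reference_expr)
  if (frac < min_overlap) {
    stop(sprintf("gene overlap %.0f%% below threshold %.0f%%",
                 100 * frac, 100 * min_overlap))
  }
  Xr <- t(reference_expr[shared, , drop = FALSE])
  ctr <- colMeans(Xr)
  scl <- apply(Xr, 2, stats::sd)
  keep <- scl > 0
  Xr <- scale(Xr[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  y_bar <- mean(y)
  yc <- y - y_bar

  if (identical(lambda, "cv")) {
    grid <- 10^seq(-4, 5, length.out = 40)
    folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), nrow(Xr))))
    mse <- vapply(grid, function(lam) {
      err <- vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        b <- ridge_solve(Xr[tr, , drop = FALSE], yc[tr], lam)
        mean((yc[!tr] - drop(Xr[!tr, , drop = FALSE] %*% b))^2)
      }, 0)
      mean(err)
    }, 0)
    lambda <- grid[which.min(mse)]
  }
  stopifnot(is.numeric(lambda), lambda >= 0)
  beta <- ridge_solve(Xr, yc, lambda)

  Zc <- scale(t(cohort_expr[shared, , drop = FALSE])[, keep, drop = FALSE],
              center = ctr[keep], scale = scl[keep])
  pred <- y_bar + drop(Zc %*% beta)
  names(pred) <- colnames(cohort_expr)
  attr(pred, "lambda") <- lambda
  attr(pred, "n_genes") <- sum(keep)
  pred
}

# Ridge coefficients via SVD: beta = V diag(d / (d^2 + lambda)) U' y.
ridge_solve <- function(X, y, lambda) {
  sv <- svd(X)
  d <- sv$d
  shrink <- d / (d^2 + lambda)
  shrink[d < .Machine$double.eps^0.5 & lambda == 0] <- 0
  drop(sv$v %*% (shrink * crossprod(sv$u, y)))
}
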