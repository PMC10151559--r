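#' Resampling-based consensus clustering of a gene subset
#'
#' Subsamples the cohort `reps` times (each resample keeps
#' `ceiling(p_item * n)` samples without replacement), clusters each
#' resample with the base clusterer — agglomerative, average linkage, on the
#' distance `1 - Pearson correlation` between sample profiles over the gene
#' subset — and records, for every sample pair and every candidate `K`, the
#' fraction of resamples in which the pair co-clusters among those in which
#' both were drawn. The resample index sets are drawn once and reused across
#' all `K`, so the per-K consensus matrices are comparable. The cluster
#' number is then chosen from the CDF of consensus values via the
#' delta-area rule (see [select_k()]), and final labels come from
#' agglomerative clustering of `1 - M` at the selected `K` (not from any
#' single base run).
#'
#' @param expr expression matrix, genes x samples.
#' @param genes gene set (or character vector) to cluster on; `NULL` uses
#'   all genes. Genes absent from the matrix are reported and dropped; an
#'   empty overlap is an error.
#' @param k_range candidate cluster numbers (default 2:9).
#' @param reps number of resamples (default 100).
#' @param p_item fraction of samples kept per resample (default 0.8).
#' @param seed RNG seed for the resample draws.
#' @param delta_threshold relative-gain threshold for [select_k()].
#' @return a `consensus_result` list: `k_range`, `consensus` (one sample x
#'   sample matrix per K, entries in `[0, 1]`, unit diagonal), `area` and
#'   `delta_area` per K, `selected_k`, `labels` (named integer vector), and
#'   `n_never_codrawn` (pairs that never appeared together; their entries
#'   are 0).
#' @export
run_consensus <- function(expr, genes = NULL, k_range = 2:9, reps = 100,
                          p_item = 0.8, seed = 1L, delta_threshold = 0.1) {
  validate_expression_matrix(expr)
  stopifnot(reps >= 2, p_item > 0, p_item <= 1)
  if (!is.null(genes)) {
    ids <- as_gene_ids(genes)
    missing <- setdiff(ids, rownames(expr))
    if (length(missing) > 0) {
      message("run_consensus: ", length(missing),
              " gene(s) absent from expression matrix")
    }
    ids <- intersect(ids, rownames(expr))
    if (length(ids) == 0) stop("no genes of the requested set are present")
    expr <- expr[ids, , drop = FALSE]
  }
  n <- ncol(expr)
  if (n < 3) stop("need at least 3 samples")
  m <- ceiling(p_item * n)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= m - 1]
  if (length(k_range) < 2) stop("need at least 2 usable candidate K values")

  idx_sets <- with_seed(seed, {
    lapply(seq_len(reps), function(r) sort(sample.int(n, m)))
  })

  # one tree per resample; cutting it gives labels for every K
  trees <- lapply(idx_sets, function(idx) {
    d <- sample_correlation_distance(expr[, idx, drop = FALSE])
    stats::hclust(stats::as.dist(d), method = "average")
  })

  codrawn <- matrix(0, n, n)
  for (idx in idx_sets) codrawn[idx, idx] <- codrawn[idx, idx] + 1

  consensus <- list()
  for (K in k_range) {
    cocount <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      lab <- stats::cutree(trees[[r]], k = K)
      idx <- idx_sets[[r]]
      cocount[idx, idx] <- cocount[idx, idx] + outer(lab, lab, "==")
    }
    M <- matrix(0, n, n, dimnames = list(colnames(expr), colnames(expr)))
    drawn <- codrawn > 0
    M[drawn] <- cocount[drawn] / codrawn[drawn]
    diag(M) <- 1
    consensus[[as.character(K)]] <- M
  }
  n_never <- sum(codrawn[upper.tri(codrawn)] == 0)
  if (n_never > 0) {
    message("run_consensus: ", n_never,
            " sample pair(s) never co-drawn; consensus entry set to 0")
  }

  areas <- vapply(consensus, function(M) consensus_cdf_area(M)$area, 0)
  sel <- select_k(areas, k_range, delta_threshold = delta_threshold)
  if (any(diff(areas) < -1e-9)) {
    warning("consensus CDF area is not non-decreasing in K")
  }

  M_sel <- consensus[[as.character(sel$selected_k)]]
  hc <- stats::hclust(stats::as.dist(1 - M_sel), method = "average")
  labels <- stats::cutree(hc, k = sel$selected_k)
  names(labels) <- colnames(expr)

  structure(list(k_range = k_range, consensus = consensus,
                 area = areas, delta_area = sel$delta_area,
                 selected_k = sel$selected_k, labels = labels,
                 n_never_codrawn = n_never,
                 params = list(reps = reps, p_item = p_item, seed = seed,
                               delta_threshold = delta_threshold)),
            class = "consensus_result")
}

# 1 - Pearson correlation between sample columns; degenerate (zero-variance)
# profiles get correlation 0 with everything.
sample_correlation_distance <- function(X) {
  cc <- suppressWarnings(stats::cor(X))
  cc[!is.finite(cc)] <- 0
  d <- 1 - cc
  diag(d) <- 0
  d
}

#' Empirical CDF and area under it for a consensus matrix
#'
#' The CDF is the empirical distribution of the `n(n-1)/2` upper-triangle
#' consensus entries; the area is the exact integral of that step function
#' over `[0, 1]` (the trapezoid rule is exact for a step function evaluated
#' at its jump points).
#'
#' @param M consensus matrix (symmetric, entries in `[0, 1]`).
#' @return `list(values = sorted entries, cdf = ecdf function, area =
#'   numeric)`.
#' @export
consensus_cdf_area <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  v <- M[upper.tri(M)]
  stopifnot(all(v >= 0 & v <= 1))
  Fhat <- stats::ecdf(v)
  grid <- sort(unique(c(0, v, 1)))
  area <- sum(Fhat(grid[-length(grid)]) * diff(grid))
  list(values = sort(v), cdf = Fhat, area = area)
}

#' Select the number of clusters from CDF areas by the delta-area rule
#'
#' With areas `A(K)` for `K = 2..Kmax`, the relative gain is defined as
#' `delta(2) = A(2)` and `delta(K) = (A(K) - A(K-1)) / A(K-1)` for `K > 2`.
#' The selected `K` is the largest candidate whose relative gain is still at
#' least `delta_threshold` — the elbow after which additional clusters yield
#' only marginal consensus gains. If no candidate reaches the threshold the
#' smallest candidate is returned. Ties (equal gains) resolve toward smaller
#' `K` because only the largest qualifying `K` is taken.
#'
#' @param areas numeric vector of CDF areas, one per candidate K.
#' @param k_range integer vector of candidate K (same length as `areas`).
#' @param delta_threshold minimum relative gain (default 0.1).
#' @return `list(selected_k, delta_area)` with `delta_area` named by K.
#' @export
select_k <- function(areas, k_range = seq_along(areas) + 1L,
                     delta_threshold = 0.1) {
  stopifnot(length(areas) == length(k_range), length(areas) >= 2)
  delta <- c(areas[1], diff(areas) / utils::head(areas, -1))
  names(delta) <- k_range
  qualifying <- k_range[delta >= delta_threshold]
  selected <- if (length(qualifying) == 0) k_range[1] else max(qualifying)
  list(selected_k = as.integer(selected), delta_area = delta)
}

#' Proportion of ambiguous clustering (PAC) diagnostic
#'
#' Fraction of upper-triangle consensus entries strictly inside
#' `(lower, upper)` — a small PAC indicates crisp consensus. Provided as an
#' optional diagnostic; K selection uses the delta-area rule.
#'
#' @param M consensus matrix.
#' @param lower,upper interval bounds (defaults 0.1 and 0.9).
#' @return numeric PAC value in `[0, 1]`.
#' @export
consensus_pac <- function(M, lower = 0.1, upper = 0.9) {
  v <- M[upper.tri(M)]
  mean(v > lower & v < upper)
}

#' Two-dimensional PCA projection of a gene subset
#'
#' Centers and unit-variance scales the selected genes, treats samples as
#' observations, and returns scores on the first two principal components —
#' the usual QC check that consensus clusters separate in expression space.
#' Constant genes are dropped with a warning; if every gene is constant all
#' coordinates are 0.
#'
#' @param expr expression matrix, genes x samples.
#' @param genes gene set or character vector (`NULL` = all genes).
#' @param labels optional per-sample cluster labels carried through for
#'   plotting.
#' @return data.frame with `sample_id`, `PC1`, `PC2` and (if given) `label`.
#' @export
pca_projection <- function(expr, genes = NULL, labels = NULL) {
  validate_expression_matrix(expr)
  if (!is.null(genes)) {
    ids <- intersect(as_gene_ids(genes), rownames(expr))
    if (length(ids) < 2) stop("need at least 2 genes for a 2-D projection")
    expr <- expr[ids, , drop = FALSE]
  }
  X <- t(expr)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene(s) from PCA")
    X <- X[, sds > 0, drop = FALSE]
  }
  out <- data.frame(sample_id = colnames(expr),
                    PC1 = 0, PC2 = 0, stringsAsFactors = FALSE)
  if (ncol(X) > 0) {
    pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
    out$PC1 <- pc$x[, 1]
    if (ncol(pc$x) >= 2) out$PC2 <- pc$x[, 2]
  }
  if (!is.null(labels)) {
    out$label <- if (!is.null(names(labels))) labels[out$sample_id] else labels
  }
  out
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("Consensus clustering over K =", paste(range(x$k_range), collapse = ".."),
      "\n  selected K:", x$selected_k, "\n  cluster sizes:",
      paste(table(x$labels), collapse = "/"), "\n  CDF areas:",
      paste(sprintf("%s:%.3f", names(x$area), x$area), collapse = " "), "\n")
  invisible(x)
}
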