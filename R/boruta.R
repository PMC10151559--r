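#' All-relevant feature selection with shadow features (Boruta)
#'
#' Iteratively appends a column-shuffled "shadow" copy of every feature still
#' in play, fits a random-forest classifier ([ranger::ranger()], impurity
#' importance), and scores a "hit" for each undecided feature whose
#' importance exceeds the maximum shadow importance in that iteration. After
#' each iteration a two-sided binomial test on the hit count (success
#' probability 0.5, Bonferroni-corrected across all input features at level
#' `alpha`) confirms features that hit significantly more than half the time
#' and rejects those that hit significantly less. Features still undecided
#' after `max_iter` iterations are tentative. Rejected features are removed
#' from subsequent forests; confirmed features stay in the model (they keep
#' competing for importance) but are no longer tested.
#'
#' @param X numeric matrix, samples x features (finite values; column names
#'   are used as feature IDs, `F1..Fp` if absent).
#' @param y target labels (coerced to factor; classification target, e.g.
#'   consensus cluster labels).
#' @param max_iter maximum number of iterations (default 100).
#' @param alpha significance level before Bonferroni correction (default
#'   0.01).
#' @param seed RNG seed; the run is deterministic given the seed
#'   (single-threaded forests).
#' @param num_trees trees per forest (default 500).
#' @return a `boruta_result` list: `confirmed`, `rejected`, `tentative`
#'   (disjoint character vectors whose union is the input features),
#'   `n_iterations`, `hits` (per-feature hit counts) and `history` (list of
#'   per-iteration importance vectors).
#' @export
boruta_select <- function(X, y, max_iter = 100, alpha = 0.01, seed = 1L,
                          num_trees = 500) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X contains non-finite values")
  if (nrow(X) < 5) stop("need at least 5 samples")
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("duplicate feature names")
  y <- factor(y)
  if (length(y) != nrow(X)) stop("y length must match nrow(X)")

  features <- colnames(X)
  p <- length(features)
  status <- stats::setNames(rep("tentative", p), features)
  hits <- stats::setNames(integer(p), features)
  history <- vector("list", max_iter)
  thr <- alpha / (2 * p)  # two-sided Bonferroni across all features
  it <- 0

  while (it < max_iter && any(status == "tentative")) {
    it <- it + 1
    keep <- features[status != "rejected"]
    Xk <- X[, keep, drop = FALSE]
    shadows <- with_seed(child_seed(seed, it), {
      S <- apply(Xk, 2, sample)
      # keep a minimum of 5 shadows so max-shadow is a stable reference
      while (ncol(S) < 5) S <- cbind(S, apply(Xk, 2, sample))
      colnames(S) <- paste0(".shadow", seq_len(ncol(S)))
      S
    })
    fit <- ranger::ranger(x = cbind(Xk, shadows), y = y,
                          num.trees = num_trees, importance = "impurity",
                          seed = child_seed(seed, 1000 + it),
                          num.threads = 1)
    imp <- fit$variable.importance
    history[[it]] <- imp
    shadow_max <- max(imp[grepl("^\\.shadow", names(imp))])
    und <- features[status == "tentative"]
    hit_now <- und[imp[und] > shadow_max]
    hits[hit_now] <- hits[hit_now] + 1

    p_up <- stats::pbinom(hits[und] - 1, it, 0.5, lower.tail = FALSE)
    p_dn <- stats::pbinom(hits[und], it, 0.5)
    status[und[p_up <= thr]] <- "confirmed"
    status[und[p_dn <= thr]] <- "rejected"
  }

  structure(list(confirmed = features[status == "confirmed"],
                 rejected = features[status == "rejected"],
                 tentative = features[status == "tentative"],
                 n_iterations = it,
                 hits = hits,
                 history = history[seq_len(it)]),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("Boruta selection after", x$n_iterations, "iteration(s):\n",
      " confirmed:", length(x$confirmed), "\n",
      " rejected: ", length(x$rejected), "\n",
      " tentative:", length(x$tentative), "\n")
  invisible(x)
}
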