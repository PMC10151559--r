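#' Specification of a synthetic tumor expression cohort
#'
#' Defines the generative model used for end-to-end validation of the
#' subtyping and scoring pipeline. The cohort has three layers of planted
#' structure that mirror what the analysis assumes of a real cohort:
#'
#' * `n_cluster_genes` subtype marker genes: each marker gene is elevated by
#'   `cluster_separation` (log2 units) in one of the `k_true` planted
#'   clusters.
#' * a per-sample latent prognostic factor `f` (standardized cluster index
#'   plus Gaussian noise) loading with `+signature_effect` on half of the
#'   `n_signature_genes` (the "up" genes) and `-signature_effect` on the
#'   other half, and driving an exponential proportional-hazards survival
#'   model with log hazard ratio `hazard_log_hr` per unit `f`.
#' * a sparse binary mutation layer whose per-sample burden is Poisson with a
#'   per-cluster mean, and ordinal stage covariates correlated with `f`.
#'
#' @param n_samples number of samples.
#' @param n_cluster_genes number of subtype marker genes (45 by default, the
#'   size of the curated metalloproteinase set in the motivating study).
#' @param n_signature_genes number of latent-factor signature genes (split
#'   evenly into up/down genes).
#' @param n_noise_genes number of unstructured noise genes.
#' @param k_true number of planted clusters.
#' @param cluster_separation between-cluster mean shift for marker genes,
#'   log2 units.
#' @param signature_effect loading of the latent factor on signature genes.
#' @param noise_sd residual standard deviation of expression values.
#' @param hazard_log_hr log hazard ratio per unit latent factor.
#' @param censor_rate target fraction of censored observations, in `[0, 1)`.
#' @param mutation_burden_means per-cluster Poisson means for mutation
#'   burden (length `k_true`).
#' @param seed master RNG seed; expanded into per-component child seeds so
#'   that adding a component never perturbs earlier draws.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 300, n_cluster_genes = 45,
                        n_signature_genes = 60, n_noise_genes = 200,
                        k_true = 3, cluster_separation = 2.5,
                        signature_effect = 1, noise_sd = 0.5,
                        hazard_log_hr = log(2), censor_rate = 0.3,
                        mutation_burden_means = c(8, 6, 4), seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_cluster_genes = as.integer(n_cluster_genes),
               n_signature_genes = as.integer(n_signature_genes),
               n_noise_genes = as.integer(n_noise_genes),
               k_true = as.integer(k_true),
               cluster_separation = cluster_separation,
               signature_effect = signature_effect,
               noise_sd = noise_sd,
               hazard_log_hr = hazard_log_hr,
               censor_rate = censor_rate,
               mutation_burden_means = rep_len(mutation_burden_means, k_true),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_samples > 0, n_cluster_genes > 0, n_signature_genes > 0,
              n_noise_genes > 0, k_true >= 1, noise_sd > 0,
              censor_rate >= 0, censor_rate < 1,
              all(mutation_burden_means > 0))
  })
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws a cohort from the generative model described in [cohort_spec()].
#' Survival times are exponential with hazard `h0 * exp(hazard_log_hr * f)`
#' where the baseline `h0 = log(2) / 36` gives a median survival of 36
#' months at `f = 0`; censoring times are uniform on `(0, c_max)` with
#' `c_max` solved so the expected censored fraction equals `censor_rate`.
#' All four endpoints (OS/PFS/DSS/DFS) are generated as independent draws of
#' the same survival model. Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return a `synthetic_cohort` list with elements `expression` (gene x
#'   sample log2 matrix), `clinical` (data.frame with four endpoint pairs and
#'   T/N/M/G/TNM stage), `mutations` (`list(matrix, burden, maf)`),
#'   `gene_sets` (two overlapping marker sets whose union is the full marker
#'   panel), and `truth` (`cluster_labels`, `latent_factor`, `up_genes`,
#'   `down_genes`, `cluster_genes`, `hazard_log_hr`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  k <- spec$k_true
  sample_ids <- sprintf("S%04d", seq_len(n))

  labels <- with_seed(child_seed(spec$seed, 1), {
    sample(rep_len(seq_len(k), n))
  })
  names(labels) <- sample_ids

  # latent prognostic factor: standardized cluster index + noise
  latent <- with_seed(child_seed(spec$seed, 2), {
    f <- as.numeric(scale(labels)) + stats::rnorm(n, 0, 0.5)
    stats::setNames(f, sample_ids)
  })

  cluster_genes <- sprintf("CLG%03d", seq_len(spec$n_cluster_genes))
  n_up <- ceiling(spec$n_signature_genes / 2)
  up_genes <- sprintf("SGU%03d", seq_len(n_up))
  down_genes <- sprintf("SGD%03d", seq_len(spec$n_signature_genes - n_up))
  noise_genes <- sprintf("NSG%03d", seq_len(spec$n_noise_genes))

  expr <- with_seed(child_seed(spec$seed, 3), {
    n_genes <- spec$n_cluster_genes + spec$n_signature_genes + spec$n_noise_genes
    baseline <- stats::rnorm(n_genes, mean = 7, sd = 1)
    mat <- matrix(stats::rnorm(n_genes * n, 0, spec$noise_sd),
                  nrow = n_genes, ncol = n)
    mat <- mat + baseline
    rownames(mat) <- c(cluster_genes, up_genes, down_genes, noise_genes)
    colnames(mat) <- sample_ids
    # each marker gene is elevated in one cluster (cycled assignment)
    marker_cluster <- ((seq_len(spec$n_cluster_genes) - 1) %% k) + 1
    for (g in seq_len(spec$n_cluster_genes)) {
      hit <- labels == marker_cluster[g]
      mat[cluster_genes[g], hit] <- mat[cluster_genes[g], hit] +
        spec$cluster_separation
    }
    for (g in up_genes) mat[g, ] <- mat[g, ] + spec$signature_effect * latent
    for (g in down_genes) mat[g, ] <- mat[g, ] - spec$signature_effect * latent
    mat
  })

  h0 <- log(2) / 36
  hazards <- h0 * exp(spec$hazard_log_hr * latent)
  clinical <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  endpoints <- c("OS", "PFS", "DSS", "DFS")
  for (i in seq_along(endpoints)) {
    se <- with_seed(child_seed(spec$seed, 10 + i), {
      t_true <- stats::rexp(n, rate = hazards)
      if (spec$censor_rate > 0) {
        cmax <- stats::uniroot(
          function(cm) mean(pmin(t_true, cm) / cm) - spec$censor_rate,
          interval = c(1e-6, 1e9), tol = 1e-8)$root
        cens <- stats::runif(n, 0, cmax)
      } else {
        cens <- rep(Inf, n)
      }
      list(time = pmin(t_true, cens), event = as.integer(t_true <= cens))
    })
    clinical[[paste0(endpoints[i], "_time")]] <- se$time
    clinical[[paste0(endpoints[i], "_event")]] <- se$event
  }

  clinical <- cbind(clinical,
                    with_seed(child_seed(spec$seed, 20), stage_covariates(latent)))

  mutations <- with_seed(child_seed(spec$seed, 30), {
    burden <- stats::rpois(n, spec$mutation_burden_means[labels])
    panel <- sprintf("MUTG%03d", 1:50)
    prob <- 2^(-(0:49) / 10)
    rows <- lapply(seq_len(n), function(i) {
      if (burden[i] == 0) return(NULL)
      counts <- stats::rmultinom(1, burden[i], prob)[, 1]
      idx <- rep(seq_along(panel), counts)
      data.frame(Hugo_Symbol = panel[idx],
                 Tumor_Sample_Barcode = sample_ids[i],
                 Variant_Classification = "Missense_Mutation",
                 stringsAsFactors = FALSE)
    })
    maf <- do.call(rbind, rows)
    mm <- mutation_matrix_from_maf(maf, samples = sample_ids)
    mm$maf <- maf
    mm
  })

  # two overlapping marker gene sets whose union is the full marker panel,
  # mirroring how two curated database sets are combined in practice
  half <- ceiling(spec$n_cluster_genes * 2 / 3)
  gene_sets <- list(
    list(name = "SYNTH_MARKERS_SET1", genes = cluster_genes[seq_len(half)]),
    list(name = "SYNTH_MARKERS_SET2",
         genes = cluster_genes[seq(max(1, half - 5), spec$n_cluster_genes)]))
  names(gene_sets) <- vapply(gene_sets, `[[`, "", "name")

  structure(list(
    expression = expr,
    clinical = clinical,
    mutations = mutations,
    gene_sets = gene_sets,
    truth = list(cluster_labels = labels, latent_factor = latent,
                 up_genes = up_genes, down_genes = down_genes,
                 cluster_genes = cluster_genes,
                 hazard_log_hr = spec$hazard_log_hr),
    spec = spec), class = "synthetic_cohort")
}

# Ordinal stage covariates correlated with the latent factor. Each covariate
# adds its own noise before binning so the correlations are imperfect, as in
# real staging data.
stage_covariates <- function(latent) {
  n <- length(latent)
  bin <- function(x, probs, labels) {
    br <- stats::quantile(x, probs = probs)
    br[1] <- -Inf; br[length(br)] <- Inf
    as.character(cut(x, breaks = br, labels = labels, include.lowest = TRUE))
  }
  data.frame(
    T = bin(latent + stats::rnorm(n, 0, 0.8), c(0, .15, .45, .8, 1),
            c("T1", "T2", "T3", "T4")),
    N = bin(latent + stats::rnorm(n, 0, 0.8), c(0, .3, .55, .8, 1),
            c("N0", "N1", "N2", "N3")),
    M = bin(latent + stats::rnorm(n, 0, 1.2), c(0, .85, 1), c("M0", "M1")),
    G = bin(latent + stats::rnorm(n, 0, 1.0), c(0, .2, .6, 1),
            c("G1", "G2", "G3")),
    TNM = bin(latent + stats::rnorm(n, 0, 0.6), c(0, .2, .5, .8, 1),
              c("I", "II", "III", "IV")),
    stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to the pipeline's on-disk input formats
#'
#' Writes `expression.tsv`, `clinical.tsv`, `mutations.maf` and
#' `gene_sets.gmt` into `dir`, so the full pipeline can be exercised purely
#' from files.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             maf = file.path(dir, "mutations.maf"),
             gmt = file.path(dir, "gene_sets.gmt"))
  write_expression_matrix(cohort$expression, paths["expression"])
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$mutations$maf, paths["maf"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(vapply(cohort$gene_sets, function(s) {
    paste(c(s$name, "synthetic marker set", s$genes), collapse = "\t")
  }, ""), paths["gmt"])
  invisible(paths)
}

#' Generate a synthetic reference drug panel
#'
#' Produces a cell-line expression matrix and log-IC50 response that is
#' linear in `n_causal` of the genes plus Gaussian noise, as a fixture for
#' ridge drug-sensitivity imputation.
#'
#' @param n_lines number of reference cell lines.
#' @param n_genes number of genes.
#' @param n_causal number of genes with nonzero effect on log-IC50 (may be 0
#'   for a null panel).
#' @param noise_sd residual standard deviation of log-IC50.
#' @param seed RNG seed.
#' @return `list(expression = gene x line matrix, log_ic50 = named numeric
#'   vector, coef = true per-gene coefficient vector)`.
#' @export
generate_drug_panel <- function(n_lines, n_genes, n_causal, noise_sd, seed = 1L) {
  stopifnot(n_causal <= n_genes, n_causal >= 0, noise_sd >= 0)
  with_seed(seed, {
    line_ids <- sprintf("CL%03d", seq_len(n_lines))
    gene_ids <- sprintf("DRG%03d", seq_len(n_genes))
    X <- matrix(stats::rnorm(n_lines * n_genes), nrow = n_lines,
                dimnames = list(line_ids, gene_ids))
    beta <- stats::setNames(numeric(n_genes), gene_ids)
    if (n_causal > 0) beta[seq_len(n_causal)] <- stats::rnorm(n_causal, 0, 1)
    y <- drop(X %*% beta) + stats::rnorm(n_lines, 0, noise_sd)
    list(expression = t(X), log_ic50 = stats::setNames(y, line_ids),
         coef = beta)
  })
}
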