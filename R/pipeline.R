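#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent R list) naming the
#' input files and every analysis threshold. Required keys: `expression`,
#' `clinical`, `gene_sets` (GMT path). Optional: `maf`, `covariates`
#' (delimited per-sample table), `output_dir`, `seed`, and parameter blocks
#' `consensus` (`k_range`, `reps`, `p_item`, `delta_threshold`), `deg`
#' (`p_threshold`, `lfc_threshold`), `boruta` (`max_iter`, `alpha`,
#' `num_trees`), `endpoints`, `roc_horizons`, `endpoint_for_ordering`,
#' `min_mutated`. Referenced files must exist at validation time.
#'
#' @param config path to a YAML file, or a named list.
#' @return a validated `pipeline_config` list with defaults filled in.
#' @export
read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else stop("config must be a file path or a list")

  defaults <- list(
    seed = 1L,
    output_dir = NULL,
    consensus = list(k_range = 2:9, reps = 100, p_item = 0.8,
                     delta_threshold = 0.1),
    deg = list(p_threshold = 0.05, lfc_threshold = 1),
    boruta = list(max_iter = 100, alpha = 0.01, num_trees = 500),
    endpoints = c("OS", "PFS", "DSS", "DFS"),
    endpoint_for_ordering = "OS",
    roc_horizons = c(12, 24, 36, 48, 60),
    min_mutated = 10)
  for (key in names(defaults)) {
    if (is.null(cfg[[key]])) {
      cfg[[key]] <- defaults[[key]]
    } else if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      for (sub in names(defaults[[key]])) {
        if (is.null(cfg[[key]][[sub]])) cfg[[key]][[sub]] <- defaults[[key]][[sub]]
      }
    }
  }
  for (key in c("expression", "clinical", "gene_sets")) {
    if (is.null(cfg[[key]])) stop("config is missing required key: ", key)
    if (!file.exists(cfg[[key]])) stop("config file does not exist: ", cfg[[key]])
  }
  for (key in c("maf", "covariates")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config file does not exist: ", cfg[[key]])
    }
  }
  with(cfg, stopifnot(deg$p_threshold > 0, deg$lfc_threshold >= 0,
                      consensus$reps >= 2, consensus$p_item > 0,
                      consensus$p_item <= 1, boruta$alpha > 0))
  cfg$consensus$k_range <- as.integer(cfg$consensus$k_range)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full subtyping and scoring pipeline
#'
#' Executes, in order: input reading and sample alignment; consensus
#' clustering of the configured gene-set union with delta-area selection of
#' K; one-vs-rest moderated differential expression between the clusters;
#' signature A/B assignment, Boruta reduction, PC1-difference scoring and
#' median dichotomization; per-endpoint log-rank comparison of the score
#' groups plus time-dependent AUC of the score; and score-vs-covariate and
#' mutation associations. Per-stage tables, the frozen score model and a
#' JSON report are written to `output_dir` when set. Any stage error aborts
#' with the stage name; outputs written by earlier stages are retained.
#'
#' @param config a `pipeline_config` (or path / list accepted by
#'   [read_pipeline_config()]).
#' @return the report, invisibly: a list with `selected_k`,
#'   `cluster_sizes`, `n_deg`, `signature_sizes`, `score_summary`,
#'   `survival` (per-endpoint log-rank p and AUCs), `associations`, and the
#'   seeds/parameters used.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    read_pipeline_config(config)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("data_io", {
    expr <- read_expression_matrix(cfg$expression)
    clinical <- read_clinical_table(cfg$clinical)
    sets <- read_gene_sets_gmt(cfg$gene_sets)
    gene_union <- gene_set_union(sets)
    samples <- align_samples(expression = colnames(expr),
                             clinical = clinical$sample_id)
    expr <- expr[, samples, drop = FALSE]
    clinical <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
    mutations <- if (!is.null(cfg$maf)) {
      mutation_matrix_from_maf(cfg$maf, samples = samples)
    } else NULL
    list(expr = expr, clinical = clinical, gene_union = gene_union,
         mutations = mutations)
  })

  cons <- stage("consensus_clustering", {
    run_consensus(inputs$expr, genes = inputs$gene_union,
                  k_range = cfg$consensus$k_range,
                  reps = cfg$consensus$reps, p_item = cfg$consensus$p_item,
                  seed = child_seed(cfg$seed, 101),
                  delta_threshold = cfg$consensus$delta_threshold)
  })

  degs <- stage("differential_expression", {
    tab <- moderated_deg_table(inputs$expr, cons$labels,
                               p_threshold = cfg$deg$p_threshold,
                               lfc_threshold = cfg$deg$lfc_threshold)
    list(table = tab,
         genes = filter_degs(tab, cfg$deg$p_threshold, cfg$deg$lfc_threshold))
  })

  scoring <- stage("signature_scoring", {
    if (length(degs$genes) == 0) stop("no genes pass the DEG thresholds")
    pair <- assign_signatures(inputs$expr, degs$genes, cons$labels,
                              inputs$clinical,
                              endpoint = cfg$endpoint_for_ordering)
    red <- reduce_signatures(inputs$expr, pair, cons$labels,
                             max_iter = cfg$boruta$max_iter,
                             alpha = cfg$boruta$alpha,
                             num_trees = cfg$boruta$num_trees,
                             seed = child_seed(cfg$seed, 202))
    fit <- fit_scores(inputs$expr, red$pair)
    list(pair = pair, reduced = red$pair, boruta = red$boruta, fit = fit)
  })
  scores <- stats::setNames(scoring$fit$table$mmp_score,
                            scoring$fit$table$sample_id)
  groups <- stats::setNames(scoring$fit$table$group,
                            scoring$fit$table$sample_id)

  surv <- stage("survival_analysis", {
    out <- list()
    for (ep in intersect(cfg$endpoints, clinical_endpoints(inputs$clinical))) {
      d <- endpoint_subset(inputs$clinical, ep)
      d <- d[d$sample_id %in% names(groups), , drop = FALSE]
      g <- groups[d$sample_id]
      if (nrow(d) == 0 || length(unique(g)) < 2) next
      lr <- logrank_test(d$time, d$event, g)
      auc <- time_dependent_auc(d$time, d$event, scores[d$sample_id],
                                horizons = cfg$roc_horizons)
      km <- lapply(split(seq_len(nrow(d)), g),
                   function(i) km_estimate(d$time[i], d$event[i], ep))
      out[[ep]] <- list(logrank = lr, auc = auc, km = km)
    }
    out
  })

  assoc <- stage("association_stats", {
    res <- list(clinicopath = clinicopath_association(scores, inputs$clinical))
    if (!is.null(inputs$mutations)) {
      res$burden <- mutation_burden_compare(inputs$mutations$burden, groups)
      res$per_gene <- per_gene_mutation_assoc(inputs$mutations, groups,
                                              min_mutated = cfg$min_mutated)
    }
    res
  })

  report <- list(
    selected_k = cons$selected_k,
    cluster_sizes = as.list(table(cons$labels)),
    cdf_area = as.list(cons$area),
    delta_area = as.list(cons$delta_area),
    n_deg = length(degs$genes),
    signature_sizes = list(
      A = length(scoring$pair$signature_A),
      B = length(scoring$pair$signature_B),
      A_reduced = length(scoring$reduced$signature_A),
      B_reduced = length(scoring$reduced$signature_B)),
    boruta = list(confirmed = length(scoring$boruta$confirmed),
                  rejected = length(scoring$boruta$rejected),
                  tentative = length(scoring$boruta$tentative),
                  iterations = scoring$boruta$n_iterations),
    score_summary = list(median = stats::median(scores),
                         n_high = sum(groups == "high"),
                         n_low = sum(groups == "low")),
    survival = lapply(surv, function(s) {
      list(logrank_chi2 = s$logrank$chi2, logrank_p = s$logrank$p,
           auc = stats::setNames(as.list(s$auc$auc),
                                 paste0("m", s$auc$horizon)))
    }),
    associations = lapply(assoc$clinicopath, function(a) {
      list(method = a$method, statistic = a$statistic, p = a$p)
    }),
    mutation = if (!is.null(assoc$burden)) {
      list(burden_p = assoc$burden$p,
           n_genes_tested = nrow(assoc$per_gene))
    } else NULL,
    params = list(seed = cfg$seed, consensus = cfg$consensus,
                  deg = cfg$deg, boruta = cfg$boruta))

  if (!is.null(out_dir)) {
    utils::write.table(
      data.frame(sample_id = names(cons$labels), cluster = cons$labels,
                 row.names = NULL),
      file.path(out_dir, "cluster_labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(degs$table, file.path(out_dir, "deg_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(scoring$fit$table,
                       file.path(out_dir, "score_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(scoring$fit$model, function(m) {
        list(genes = m$genes, center = as.list(m$center),
             scale = as.list(m$scale), rotation = as.list(m$rotation))
      }),
      file.path(out_dir, "score_model.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  invisible(structure(c(report, list(
    consensus = cons, deg_table = degs$table, deg_genes = degs$genes,
    signatures = scoring$pair, signatures_reduced = scoring$reduced,
    score_fit = scoring$fit, survival_detail = surv,
    associations_detail = assoc)), class = "pipeline_report"))
}
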