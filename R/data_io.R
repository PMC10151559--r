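#' Read a gene-by-sample expression matrix from delimited text
#'
#' The file must have a header row of sample identifiers and gene identifiers
#' in the first column. Values are expected on the log2 scale. Duplicate gene
#' rows are collapsed by their mean (with a message); duplicate sample columns
#' are an error. Any cell that does not parse as a finite number is a parse
#' error that names the offending gene and sample.
#'
#' @param path path to a `.tsv`/`.csv` (or other delimited) file.
#' @param delimiter field separator. Default `NULL` auto-detects from the
#'   file extension: `,` for `.csv`, tab otherwise.
#' @return numeric matrix, genes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_expression_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- delimiter %||% detect_delimiter(path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2) stop("expression file has no sample columns: ", path)
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric or non-finite value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 samples[bad[1, 2]]))
  }
  rownames(num) <- genes
  colnames(num) <- samples
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    message("collapsing ", length(dup), " duplicated gene ID(s) by mean: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "")
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
  }
  validate_expression_matrix(num)
}

#' Validate an expression matrix
#'
#' Checks the container invariants: unique gene and sample identifiers,
#' all values finite, at least 2 genes and 3 samples.
#'
#' @param mat numeric matrix with rownames (genes) and colnames (samples).
#' @return the matrix, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample IDs")
  if (!all(is.finite(mat))) stop("expression matrix contains non-finite values")
  if (nrow(mat) < 2) stop("need at least 2 genes")
  if (ncol(mat) < 3) stop("need at least 3 samples")
  mat
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]: header row of sample IDs, gene IDs
#' in the first column.
#'
#' @param mat numeric matrix, genes x samples.
#' @param path output path.
#' @param delimiter field separator; default auto-detected from extension.
#' @export
write_expression_matrix <- function(mat, path, delimiter = NULL) {
  delim <- delimiter %||% detect_delimiter(path)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

detect_delimiter <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Read gene sets from a GMT file
#'
#' Each non-empty line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Lines with fewer than three fields are a format error reported with the
#' line number. Sets are returned in file order.
#'
#' @param path path to a GMT file.
#' @return a list of gene sets, each a `list(name = , genes = )` with unique
#'   gene IDs; the list is named by set name.
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- lapply(keep, function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields", i))
    }
    list(name = fields[1], genes = unique(fields[-(1:2)]))
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Union of gene sets
#'
#' Combines several gene sets (e.g. the two curated metalloproteinase sets)
#' into one, preserving first-seen gene order.
#'
#' @param sets list of gene sets as returned by [read_gene_sets_gmt()].
#' @param name name for the combined set.
#' @return a single gene set `list(name = , genes = )`.
#' @export
gene_set_union <- function(sets, name = "union") {
  stopifnot(length(sets) >= 1)
  genes <- unique(unlist(lapply(sets, `[[`, "genes"), use.names = FALSE))
  list(name = name, genes = genes)
}

# Accept either a gene set object or a plain character vector of gene IDs.
as_gene_ids <- function(genes) {
  if (is.list(genes) && !is.null(genes$genes)) genes$genes else as.character(genes)
}

#' Read a per-sample clinical table
#'
#' Expects a `sample_id` column (or the first column is taken as sample IDs),
#' survival endpoints as `<EP>_time` / `<EP>_event` column pairs (months;
#' event 1 = observed), and optional ordinal covariates such as T/N/M/G/TNM
#' stage. Missing values are allowed per endpoint: a sample lacking one
#' endpoint's time is simply excluded from analyses of that endpoint (see
#' [endpoint_subset()]).
#'
#' @param path path to a delimited file.
#' @param delimiter field separator; default auto-detected from extension.
#' @return a data.frame with a `sample_id` column.
#' @export
read_clinical_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- delimiter %||% detect_delimiter(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (!"sample_id" %in% colnames(df)) colnames(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in clinical table")
  validate_clinical_table(df)
}

validate_clinical_table <- function(df) {
  for (ep in clinical_endpoints(df)) {
    tm <- df[[paste0(ep, "_time")]]
    ev <- df[[paste0(ep, "_event")]]
    if (any(tm < 0, na.rm = TRUE)) {
      stop("negative ", ep, "_time in clinical table")
    }
    if (!all(ev %in% c(0, 1, NA))) {
      stop(ep, "_event values must be 0 or 1")
    }
  }
  df
}

#' List the survival endpoints present in a clinical table
#'
#' @param clinical data.frame from [read_clinical_table()].
#' @return character vector of endpoint names (e.g. `c("OS", "PFS")`) for
#'   which both `<EP>_time` and `<EP>_event` columns exist.
#' @export
clinical_endpoints <- function(clinical) {
  tm <- sub("_time$", "", grep("_time$", colnames(clinical), value = TRUE))
  ev <- sub("_event$", "", grep("_event$", colnames(clinical), value = TRUE))
  intersect(tm, ev)
}

#' Extract complete cases for one survival endpoint
#'
#' @param clinical clinical data.frame.
#' @param endpoint endpoint name, e.g. `"OS"`.
#' @return data.frame with columns `sample_id`, `time`, `event`, restricted
#'   to samples with non-missing time and event for that endpoint.
#' @export
endpoint_subset <- function(clinical, endpoint) {
  tc <- paste0(endpoint, "_time")
  ec <- paste0(endpoint, "_event")
  if (!all(c(tc, ec) %in% colnames(clinical))) {
    stop("endpoint not present in clinical table: ", endpoint)
  }
  out <- data.frame(sample_id = clinical$sample_id,
                    time = clinical[[tc]], event = clinical[[ec]],
                    stringsAsFactors = FALSE)
  out[stats::complete.cases(out$time, out$event), , drop = FALSE]
}

#' Reduce a MAF-like mutation table to a binary gene-by-sample matrix
#'
#' Rows whose `Variant_Classification` is in `excluded_classes` do not count.
#' The per-sample burden is the number of qualifying variant rows (several
#' variants in one gene all count toward burden, while the matrix entry is
#' binary). Samples listed in `samples` but absent from the MAF get burden 0
#' and all-zero matrix columns.
#'
#' @param path path to a tab-delimited MAF file (columns `Hugo_Symbol`,
#'   `Tumor_Sample_Barcode`, `Variant_Classification` required), or a
#'   data.frame with those columns.
#' @param excluded_classes variant classes that do not qualify. The default
#'   drops the usual non-coding/silent classes.
#' @param samples optional cohort sample IDs used to zero-fill.
#' @return `list(matrix = binary gene x sample matrix, burden = named integer
#'   vector of qualifying-variant counts per sample)`.
#' @export
mutation_matrix_from_maf <- function(path,
                                     excluded_classes = c(
                                       "Silent", "Intron", "3'UTR", "5'UTR",
                                       "3'Flank", "5'Flank", "IGR", "RNA"),
                                     samples = NULL) {
  maf <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "\"",
                      comment.char = "#")
  }
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_cols <- setdiff(required, colnames(maf))
  if (length(missing_cols) > 0) {
    stop("MAF is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  qual <- maf[!(maf$Variant_Classification %in% excluded_classes), , drop = FALSE]
  sample_ids <- unique(c(as.character(qual$Tumor_Sample_Barcode),
                         as.character(samples)))
  gene_ids <- unique(as.character(qual$Hugo_Symbol))
  mat <- matrix(0L, nrow = length(gene_ids), ncol = length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
  burden <- stats::setNames(integer(length(sample_ids)), sample_ids)
  if (nrow(qual) > 0) {
    counts <- table(factor(qual$Hugo_Symbol, levels = gene_ids),
                    factor(qual$Tumor_Sample_Barcode, levels = sample_ids))
    mat[] <- as.integer(counts > 0)
    burden[] <- as.integer(colSums(counts))
  }
  list(matrix = mat, burden = burden)
}

#' Intersect sample IDs across tables
#'
#' All downstream analyses run on the intersection of the sample IDs present
#' in every supplied table; the number of IDs dropped from each input is
#' reported with a message.
#'
#' @param ... character vectors of sample IDs (named arguments are used in
#'   the log message).
#' @return character vector of common sample IDs, in the order of the first
#'   argument.
#' @export
align_samples <- function(...) {
  lists <- list(...)
  stopifnot(length(lists) >= 1)
  common <- Reduce(intersect, lists)
  nms <- names(lists) %||% rep("", length(lists))
  for (i in seq_along(lists)) {
    dropped <- length(lists[[i]]) - length(common)
    if (dropped > 0) {
      message("align_samples: dropping ", dropped, " sample(s) from ",
              if (nzchar(nms[i])) nms[i] else paste0("input ", i))
    }
  }
  if (length(common) == 0) stop("no samples shared across inputs")
  lists[[1]][lists[[1]] %in% common]
}
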