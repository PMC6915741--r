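#' Lifespan expression dataset
#'
#' Bundles a log2 expression matrix (genes in rows, samples in columns) with
#' aligned per-sample metadata: brain region, ordinal developmental stage,
#' age, post-mortem interval (PMI, hours) and RNA integrity number (RIN).
#'
#' @param expr Numeric matrix of log2 expression values with gene identifiers
#'   as row names and sample identifiers as column names.
#' @param meta Data frame with one row per sample and columns `sample_id`,
#'   `region`, `stage` (integer, member of `stage_order`), and optionally
#'   `age`, `pmi`, `rin`.
#' @param stage_order Integer vector giving the ordered set of developmental
#'   stages the analysis spans. Defaults to the sorted unique stages present.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `expr`, `meta` and `stage_order`.
#' @export
expression_dataset <- function(expr, meta, stage_order = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix (genes x samples)")
  }
  if (nrow(expr) == 0L) stop("`expr` contains no genes")
  if (is.null(rownames(expr))) stop("`expr` must have gene identifiers as row names")
  if (anyDuplicated(rownames(expr))) {
    dup <- unique(rownames(expr)[duplicated(rownames(expr))])
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (is.null(colnames(expr))) stop("`expr` must have sample identifiers as column names")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "region", "stage")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (ncol(expr) != nrow(meta)) {
    stop("expression has ", ncol(expr), " samples but metadata has ", nrow(meta), " rows")
  }
  missing_samples <- setdiff(meta$sample_id, colnames(expr))
  if (length(missing_samples)) {
    stop("metadata sample(s) missing from expression matrix: ",
         paste(utils::head(missing_samples, 5), collapse = ", "))
  }
  expr <- expr[, as.character(meta$sample_id), drop = FALSE]
  if (anyNA(meta$stage) || anyNA(meta$region)) {
    stop("metadata contains missing stage or region labels")
  }
  meta$stage <- as.integer(meta$stage)
  meta$region <- as.character(meta$region)
  if (is.null(stage_order)) {
    stage_order <- sort(unique(meta$stage))
  }
  stage_order <- as.integer(stage_order)
  unknown <- setdiff(meta$stage, stage_order)
  if (length(unknown)) {
    stop("stage label(s) outside the declared stage order: ",
         paste(unknown, collapse = ", "))
  }
  structure(
    list(expr = expr, meta = meta, stage_order = stage_order),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  cat("  regions:", paste(sort(unique(x$meta$region)), collapse = ", "), "\n")
  cat("  stages:", paste(x$stage_order, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$expr)

#' Subset an expression dataset by sample
#'
#' @param data An [expression_dataset()].
#' @param samples Character vector of sample identifiers to keep.
#' @return A new `expression_dataset` restricted to `samples`.
#' @export
subset_samples <- function(data, samples) {
  stopifnot(inherits(data, "expression_dataset"))
  keep <- data$meta$sample_id %in% samples
  expression_dataset(data$expr[, data$meta$sample_id[keep], drop = FALSE],
                     data$meta[keep, , drop = FALSE],
                     stage_order = data$stage_order)
}

#' Adjacent-stage transition labels
#'
#' Transitions are consecutive members of the declared stage order, labelled
#' `"s-t"` (e.g. `"7-8"`).
#'
#' @param stage_order Integer vector of ordered stages.
#' @return Character vector of length `length(stage_order) - 1`.
#' @export
stage_transitions <- function(stage_order) {
  stage_order <- as.integer(stage_order)
  if (length(stage_order) < 2) return(character(0))
  paste0(stage_order[-length(stage_order)], "-", stage_order[-1])
}

#' Read an expression dataset from TSV files
#'
#' The expression file is a TSV with the gene identifier in the first column
#' and one column per sample; the metadata file is a TSV with columns
#' `sample_id`, `region`, `stage` and optionally `age`, `pmi`, `rin`.
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Path to the metadata TSV.
#' @param stage_order Optional explicit stage order (integer vector).
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(expr_path, meta_path, stage_order = NULL) {
  tab <- utils::read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("expression file contains no genes: ", expr_path)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene identifiers in ", expr_path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  expr <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(expr)) stop("non-numeric expression values in ", expr_path)
  rownames(expr) <- genes
  meta <- utils::read.delim(meta_path, check.names = FALSE, stringsAsFactors = FALSE)
  expression_dataset(expr, meta, stage_order = stage_order)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression_tsv()].
#'
#' @param data An [expression_dataset()].
#' @param expr_path Output path for the expression TSV.
#' @param meta_path Output path for the metadata TSV.
#' @return Invisibly, a character vector of the two paths written.
#' @export
write_expression_tsv <- function(data, expr_path, meta_path) {
  stopifnot(inherits(data, "expression_dataset"))
  tab <- data.frame(gene = rownames(data$expr), data$expr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, meta_path))
}
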