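#' Container for a TF-ID (barcode) by cell UMI count matrix
#'
#' The enrichment library of a barcoded TF overexpression screen is summarised
#' as a TF-ID x cell matrix of UMI counts. Each TF-ID row carries the barcode
#' sequence and the TF it tags.
#'
#' @param counts non-negative integer matrix (TF-ID x cell); coerced to a
#'   sparse `dgCMatrix`.
#' @param tfids data.frame with columns `tfid` (row names of `counts`),
#'   `barcode` (DNA sequence) and `tf` (TF name; the control construct, e.g.
#'   mCherry, is a TF-ID like any other).
#' @param cells character vector of cell barcodes (column names of `counts`).
#' @return object of class `tfid_counts`.
#' @export
tfid_counts <- function(counts, tfids, cells = colnames(counts)) {
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("TF-ID counts must be non-negative")
  stopifnot(is.data.frame(tfids), all(c("tfid", "tf") %in% names(tfids)))
  if (nrow(tfids) != nrow(counts)) {
    stop("format error: tfids table does not match count matrix rows")
  }
  rownames(counts) <- tfids$tfid
  colnames(counts) <- cells
  structure(list(counts = counts, tfids = tfids, cells = cells),
            class = "tfid_counts")
}

#' Container for a gene by cell UMI count matrix
#'
#' @param counts non-negative integer matrix (gene x cell).
#' @param genes data.frame with columns `gene` and logical flags `is_mito`,
#'   `is_ribo`, `is_coding` used by QC.
#' @param cells character vector of cell barcodes.
#' @param norm optional normalized layer (same shape as `counts`).
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(counts, genes, cells = colnames(counts), norm = NULL) {
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("expression counts must be non-negative")
  stopifnot(is.data.frame(genes), "gene" %in% names(genes))
  if (nrow(genes) != nrow(counts)) {
    stop("format error: gene table does not match count matrix rows")
  }
  rownames(counts) <- genes$gene
  colnames(counts) <- cells
  structure(list(counts = counts, genes = genes, cells = cells, norm = norm),
            class = "expr_matrix")
}

#' @export
print.tfid_counts <- function(x, ...) {
  cat(sprintf("tfid_counts: %d TF-IDs x %d cells (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$norm)) "" else " (+ normalized layer)"))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d TFs (%s), %d genes, %d batches\n",
              nrow(x$tf_params),
              paste(sprintf("%s=%d", names(table(x$tf_params$class)),
                            as.integer(table(x$tf_params$class))), collapse = ", "),
              x$config$n_genes, x$config$n_batches))
  invisible(x)
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d cells, %d genes, %d TF-IDs\n",
              nrow(x$truth), nrow(x$expr$counts), nrow(x$tfid$counts)))
  invisible(x)
}
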