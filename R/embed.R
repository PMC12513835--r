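#' Log-normalize a count matrix
#'
#' Scales each cell to a fixed total (default 10,000) and applies
#' `log1p`. Cells with zero total counts cannot be normalized and are
#' dropped with a warning.
#'
#' @param expr an [expr_matrix()].
#' @param scale_factor per-cell target total.
#' @return the [expr_matrix()] with the `norm` layer filled.
#' @export
normalize_log1p <- function(expr, scale_factor = 1e4) {
  stopifnot(inherits(expr, "expr_matrix"))
  total <- Matrix::colSums(expr$counts)
  if (any(total == 0)) {
    warning(sum(total == 0), " all-zero cell(s) excluded from normalization")
    keep <- total > 0
    expr$counts <- expr$counts[, keep, drop = FALSE]
    expr$cells <- expr$cells[keep]
    total <- total[keep]
  }
  expr$norm <- expr$counts %*% Matrix::Diagonal(x = scale_factor / total)
  expr$norm@x <- log1p(expr$norm@x)
  dimnames(expr$norm) <- dimnames(expr$counts)
  expr
}

#' Regress out control-cell heterogeneity per batch
#'
#' Per batch, a PCA subspace is fitted on control cells and every cell's
#' reconstruction within that subspace (after centering on the control mean)
#' is subtracted. Variation shared with controls is thereby removed while
#' TF-specific signal orthogonal to the control subspace is left intact.
#'
#' @param norm normalized matrix (gene x cell), e.g. `expr$norm`.
#' @param cells data.frame with `cell_id`, `batch` and `assigned_tf`
#'   (`"control"` marks control cells).
#' @param k_ctrl dimension of the control subspace (default 20).
#' @param min_controls minimum control cells per batch; batches below this
#'   are skipped with a warning (cells returned centered but unprojected).
#' @return dense residual matrix (gene x cell), same dimnames as `norm`.
#' @export
regress_control_heterogeneity <- function(norm, cells, k_ctrl = 20,
                                          min_controls = 20) {
  X <- as.matrix(norm)
  cells <- cells[match(colnames(X), cells$cell_id), ]
  res <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  for (b in unique(cells$batch)) {
    idx <- which(cells$batch == b)
    ctrl <- idx[cells$assigned_tf[idx] == "control"]
    Xb <- X[, idx, drop = FALSE]
    if (length(ctrl) < min_controls) {
      warning("batch ", b, " skipped: only ", length(ctrl), " control cells")
      res[, idx] <- Xb - rowMeans(Xb)
      next
    }
    mu <- rowMeans(X[, ctrl, drop = FALSE])
    Xc <- X[, ctrl, drop = FALSE] - mu
    sv <- svd(Xc, nu = min(k_ctrl, min(dim(Xc))), nv = 0)
    k <- min(k_ctrl, sum(sv$d > sv$d[1] * 1e-10))
    V <- sv$u[, seq_len(k), drop = FALSE]         # gene x k control loadings
    Xd <- Xb - mu
    res[, idx] <- Xd - V %*% (crossprod(V, Xd))
  }
  res
}

#' Joint PCA embedding across batches
#'
#' Applies per-gene per-batch centering and then a single PCA across all
#' cells; with one batch this reduces to plain PCA of the input.
#'
#' @param residuals gene x cell matrix (e.g. from
#'   [regress_control_heterogeneity()]).
#' @param batch batch label per cell (single batch assumed when `NULL`).
#' @param n_pcs number of components (capped at the matrix rank).
#' @return an object of class `embedding` with `scores` (cell x PC),
#'   `loadings` (gene x PC), `sdev`, `var_explained` and `fitted_on`.
#' @export
integrate_batches <- function(residuals, batch = NULL, n_pcs = 200) {
  X <- as.matrix(residuals)
  if (!is.null(batch)) {
    stopifnot(length(batch) == ncol(X))
    for (b in unique(batch)) {
      idx <- batch == b
      X[, idx] <- X[, idx, drop = FALSE] - rowMeans(X[, idx, drop = FALSE])
    }
  }
  embed_pca(X, n_pcs = n_pcs, fitted_on = "integrated")
}

#' Plain PCA embedding of a normalized gene x cell matrix
#'
#' @param norm gene x cell matrix.
#' @param n_pcs number of components (capped at rank).
#' @param fitted_on descriptor stored in the result.
#' @return an `embedding` object (see [integrate_batches()]).
#' @export
embed_pca <- function(norm, n_pcs = 50, fitted_on = "all") {
  X <- t(as.matrix(norm))                         # cells x genes
  n_pcs <- min(n_pcs, nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  keep <- pc$sdev[seq_len(n_pcs)] > pc$sdev[1] * 1e-12
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 loadings = pc$rotation[, keep, drop = FALSE],
                 sdev = pc$sdev[seq_len(n_pcs)][keep],
                 var_explained = pc$sdev[seq_len(n_pcs)][keep]^2 /
                   sum(pc$sdev^2),
                 n_pcs = sum(keep), fitted_on = fitted_on),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d cells x %d PCs (fitted on %s)\n",
              nrow(x$scores), x$n_pcs, x$fitted_on))
  invisible(x)
}

#' Overall transcriptomic change per cell
#'
#' The negative Pearson correlation between each cell's embedding score
#' vector and the centroid of control cells, adjusted by subtracting the
#' mean of the same statistic over control cells (so controls average
#' exactly zero).
#'
#' @param embedding an `embedding`.
#' @param control_ids cell ids of control cells (at least 2).
#' @return named numeric vector of change values; cells with a zero-variance
#'   score vector get `NA` and are listed in `attr(,"flagged")`.
#' @export
transcriptomic_change <- function(embedding, control_ids) {
  scores <- embedding$scores
  ctrl <- intersect(control_ids, rownames(scores))
  if (length(ctrl) < 2) stop("need at least 2 control cells in the embedding")
  centroid <- colMeans(scores[ctrl, , drop = FALSE])
  sds <- apply(scores, 1, sd)
  flagged <- rownames(scores)[sds == 0]
  raw <- rep(NA_real_, nrow(scores))
  ok <- sds > 0
  if (sd(centroid) == 0) stop("control centroid has zero variance")
  raw[ok] <- -as.numeric(cor(t(scores[ok, , drop = FALSE]), centroid))
  names(raw) <- rownames(scores)
  change <- raw - mean(raw[ctrl], na.rm = TRUE)
  attr(change, "flagged") <- flagged
  change
}

#' Minimal functional dose
#'
#' The smallest dose at which a monotone (isotonic) smoother of
#' transcriptomic change versus dose first exceeds the threshold; `NA` when
#' the smoothed change never does.
#'
#' @param doses,changes per-cell vectors (at least 10 cells).
#' @param threshold change threshold (default 0.23, the functional-change
#'   cutoff).
#' @return a dose, or `NA_real_`.
#' @export
minimal_functional_dose <- function(doses, changes, threshold = 0.23) {
  stopifnot(length(doses) == length(changes))
  if (length(doses) < 10) stop("need at least 10 cells")
  ord <- order(doses)
  iso <- isoreg(doses[ord], changes[ord])
  above <- iso$yf > threshold
  if (!any(above)) return(NA_real_)
  doses[ord][which(above)[1]]
}

#' Normalize expression levels against a housekeeping set
#'
#' Divides values by the mean of the housekeeping levels, putting exogenous
#' dose, endogenous expression and physiological reference tables on a
#' common scale. If `expected` housekeeping genes are supplied, missing ones
#' are reported; at least `min_hk` must remain.
#'
#' @param values numeric vector/matrix to normalize.
#' @param hk_values numeric vector of housekeeping expression levels
#'   (named by gene when `expected` is used).
#' @param expected optional character vector of expected housekeeping genes.
#' @param min_hk minimum housekeeping genes required (default 5).
#' @return normalized values; missing housekeeping genes in
#'   `attr(,"missing_hk")`.
#' @export
normalize_to_housekeeping <- function(values, hk_values, expected = NULL,
                                      min_hk = 5) {
  missing_hk <- character(0)
  if (!is.null(expected)) {
    missing_hk <- setdiff(expected, names(hk_values))
    hk_values <- hk_values[intersect(expected, names(hk_values))]
    if (length(hk_values) < min_hk) {
      stop("only ", length(hk_values), " housekeeping genes present (need >= ",
           min_hk, "); missing: ", paste(missing_hk, collapse = ", "))
    }
  }
  out <- values / mean(hk_values)
  attr(out, "missing_hk") <- missing_hk
  out
}

#' Compare a minimal functional dose to physiological expression
#'
#' Checks whether the minimal functional dose falls inside the 5-95%
#' quantile band of the physiological expression of the top-expressing cell
#' type for that TF. Quantiles are pure order statistics (type 1).
#'
#' @param min_dose minimal functional dose (housekeeping-normalized).
#' @param physio_table long data.frame with columns `tf`, `cell_type`,
#'   `value` (per-cell or per-donor expression levels).
#' @param tf TF name.
#' @param band quantile band (default `c(0.05, 0.95)`).
#' @return list with `within_range`, `top_cell_type`, `band`; `NULL` when
#'   the TF is absent from the table.
#' @export
compare_physiological <- function(min_dose, physio_table, tf,
                                  band = c(0.05, 0.95)) {
  stopifnot(all(c("tf", "cell_type", "value") %in% names(physio_table)))
  tab <- physio_table[physio_table$tf == tf, ]
  if (nrow(tab) == 0) return(NULL)
  means <- tapply(tab$value, tab$cell_type, mean)
  top <- names(means)[which.max(means)]
  v <- tab$value[tab$cell_type == top]
  q <- quantile(v, band, type = 1, names = FALSE)
  list(within_range = !is.na(min_dose) && min_dose >= q[1] && min_dose <= q[2],
       top_cell_type = top, band = q)
}

#' Pairwise cellular similarity
#'
#' Pairwise Pearson correlation between cells in the top principal
#' components of the embedding.
#'
#' @param embedding an `embedding`.
#' @param n_pcs number of PCs to use (default 50, capped at available PCs).
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   cells flagged in `attr(,"flagged")` (their rows are `NA`).
#' @export
pairwise_cell_similarity <- function(embedding, n_pcs = 50) {
  S <- embedding$scores[, seq_len(min(n_pcs, embedding$n_pcs)), drop = FALSE]
  if (nrow(S) < 2) stop("need at least 2 cells")
  sds <- apply(S, 1, sd)
  flagged <- rownames(S)[sds == 0]
  M <- suppressWarnings(cor(t(S)))
  if (length(flagged)) M[flagged, ] <- M[, flagged] <- NA_real_
  diag(M) <- 1
  attr(M, "flagged") <- flagged
  M
}

#' Expression-bin-matched module score
#'
#' Mean normalized expression of a gene set minus the mean of random
#' control genes drawn (without replacement, seeded) from expression bins
#' matched to the set genes — the construction behind lineage scores such
#' as an adipocyte "adiposcore".
#'
#' @param norm normalized gene x cell matrix.
#' @param gene_set character vector of at least 2 genes present in `norm`.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes drawn per set gene (default 100, capped at
#'   bin size).
#' @param seed integer seed for the control draw.
#' @return named numeric score per cell, control genes in
#'   `attr(,"control_genes")`.
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1) {
  norm <- as.matrix(norm)
  gene_set <- intersect(gene_set, rownames(norm))
  if (length(gene_set) < 2) stop("gene set must contain at least 2 genes")
  avg <- rowMeans(norm)
  n_bins <- min(n_bins, nrow(norm))
  # bins of (nearly) equal size over the rank of average expression,
  # ties broken by gene index
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk / (nrow(norm) / n_bins))
  names(bin) <- rownames(norm)
  set.seed(seed)
  ctrl_pool <- character(0)
  for (g in gene_set) {
    pool <- setdiff(names(bin)[bin == bin[g]], g)
    ctrl_pool <- c(ctrl_pool, sample(pool, min(n_ctrl, length(pool))))
  }
  ctrl_pool <- unique(ctrl_pool)
  score <- colMeans(norm[gene_set, , drop = FALSE]) -
    colMeans(norm[ctrl_pool, , drop = FALSE])
  attr(score, "control_genes") <- ctrl_pool
  score
}
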