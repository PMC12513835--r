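#' Flag non-functional cells
#'
#' TF-overexpressing cells transcriptomically indistinguishable from
#' controls: overall change at or below the functional threshold.
#'
#' @param changes per-cell change values.
#' @param threshold functional-change cutoff (default 0.23).
#' @return logical vector, `TRUE` = non-functional.
#' @export
label_nonfunctional <- function(changes, threshold = 0.23) {
  changes <= threshold
}

# k-nearest-neighbour index matrix by exact search; ties broken by index
knn_index <- function(scores, k) {
  n <- nrow(scores)
  D <- as.matrix(dist(scores))
  diag(D) <- Inf
  t(vapply(seq_len(n), function(i) {
    order(D[i, ], seq_len(n))[seq_len(k)]
  }, integer(k)))
}

#' Graph-based clustering on a shared-nearest-neighbour graph
#'
#' Builds a k-NN graph in embedding space, weights edges by the Jaccard
#' overlap of neighbourhoods (pruning weak overlaps) and partitions the
#' graph with modularity (Louvain) community detection at the given
#' resolution. Deterministic for a fixed seed.
#'
#' @param embedding an `embedding` or a cell x dimension score matrix.
#' @param resolution modularity resolution (default 1.2).
#' @param k_nn neighbours per cell (default 20; reduced with a warning when
#'   there are fewer cells).
#' @param seed integer seed.
#' @param prune minimum Jaccard overlap kept as an edge (default 1/15).
#' @return data.frame with `cell_id` and integer `cluster`.
#' @export
cluster_cells <- function(embedding, resolution = 1.2, k_nn = 20, seed = 1,
                          prune = 1 / 15) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  n <- nrow(scores)
  if (n <= k_nn) {
    warning("k_nn reduced to ", n - 1L, " (only ", n, " cells)")
    k_nn <- n - 1L
  }
  nn <- knn_index(scores, k_nn)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  edges <- list()
  for (i in seq_len(n)) {
    for (j in nn[i, ]) {
      if (j > i) {
        w <- length(intersect(sets[[i]], sets[[j]])) /
          length(union(sets[[i]], sets[[j]]))
        if (w >= prune) edges[[length(edges) + 1]] <- c(i, j, w)
      }
    }
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em[, 1:2, drop = FALSE] |>
                                     apply(2, as.integer), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- em[, 3]
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  data.frame(cell_id = rownames(scores),
             cluster = as.integer(igraph::membership(cl)),
             stringsAsFactors = FALSE)
}

#' Flag control clusters by composition
#'
#' A cluster is a control cluster when fewer than `control_frac` of its
#' cells originate from the focal TF (equivalently, it is predominantly
#' composed of control cells).
#'
#' @param assignment data.frame `cell_id`, `cluster`.
#' @param is_focal logical per cell (aligned with `assignment`), `TRUE` for
#'   cells of the focal TF (or, atlas-wide, any TF cell).
#' @param control_frac threshold on the focal fraction (default 0.6,
#'   strict: a cluster with exactly 60% focal cells is functional).
#' @return named logical vector per cluster, `TRUE` = control cluster.
#' @export
identify_control_clusters <- function(assignment, is_focal,
                                      control_frac = 0.6) {
  stopifnot(length(is_focal) == nrow(assignment))
  frac <- tapply(is_focal, assignment$cluster, mean)
  setNames(as.vector(frac) < control_frac, names(frac))
}

#' Find TFs driving heterogeneous cell states
#'
#' A TF is a candidate for stochastic/heterogeneous reprogramming when at
#' least two functionally distinct (non-control) clusters each hold a
#' fraction of that TF's cells inside the `band`; TFs represented by fewer
#' than `min_cells` cells in the clustering are excluded.
#'
#' @param assignment data.frame `cell_id`, `cluster`.
#' @param cells data.frame `cell_id`, `assigned_tf`.
#' @param control_clusters named logical from [identify_control_clusters()].
#' @param min_cells minimum cells per TF (default 30).
#' @param band fraction band (default `c(0.05, 0.95)`).
#' @return data.frame per TF: `tf`, `n_cells`, `n_spread_clusters`,
#'   `candidate`.
#' @export
find_heterogeneous_tfs <- function(assignment, cells, control_clusters,
                                   min_cells = 30, band = c(0.05, 0.95)) {
  m <- merge(assignment, cells[, c("cell_id", "assigned_tf")], by = "cell_id")
  m <- m[!m$assigned_tf %in% c("control", "doublet", "unassigned"), ]
  functional <- names(control_clusters)[!control_clusters]
  out <- lapply(split(m, m$assigned_tf), function(d) {
    n <- nrow(d)
    tab <- table(factor(as.character(d$cluster), levels = functional)) / n
    spread <- sum(tab >= band[1] & tab <= band[2])
    data.frame(tf = d$assigned_tf[1], n_cells = n,
               n_spread_clusters = spread,
               candidate = n >= min_cells && spread >= 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Recluster one TF with its batch-paired controls
#'
#' Pools a TF's cells with control cells from the same batches, re-embeds
#' the pooled set by PCA and reclusters; control clusters are re-derived by
#' the composition rule with the TF as focal group.
#'
#' @param norm normalized gene x cell matrix.
#' @param cells data.frame `cell_id`, `assigned_tf`, `batch`.
#' @param tf focal TF.
#' @param n_pcs PCs for the pooled embedding (default 30).
#' @param resolution,k_nn,seed passed to [cluster_cells()].
#' @param control_frac passed to [identify_control_clusters()].
#' @return list with `assignment`, `control_clusters`, `embedding`,
#'   `cell_ids`.
#' @export
recluster_tf_with_controls <- function(norm, cells, tf, n_pcs = 30,
                                       resolution = 1.2, k_nn = 20,
                                       seed = 1, control_frac = 0.6) {
  tf_cells <- cells$cell_id[cells$assigned_tf == tf]
  if (!length(tf_cells)) stop("no cells assigned to ", tf)
  batches <- unique(cells$batch[cells$assigned_tf == tf])
  ctrl_cells <- cells$cell_id[cells$assigned_tf == "control" &
                                cells$batch %in% batches]
  if (!length(ctrl_cells)) stop("no batch-paired control cells for ", tf)
  ids <- c(tf_cells, ctrl_cells)
  emb <- embed_pca(norm[, ids, drop = FALSE], n_pcs = n_pcs,
                   fitted_on = paste0("pooled:", tf))
  assignment <- cluster_cells(emb, resolution = resolution, k_nn = k_nn,
                              seed = seed)
  flags <- identify_control_clusters(
    assignment, assignment$cell_id %in% tf_cells, control_frac = control_frac)
  list(assignment = assignment, control_clusters = flags, embedding = emb,
       cell_ids = ids)
}

#' Negative-binomial differential expression with a batch covariate
#'
#' Per-gene NB generalized linear models (log link) with group and batch
#' terms, tagwise dispersion estimation and a likelihood-ratio test on the
#' group term, as implemented in edgeR; Benjamini-Hochberg FDR across
#' genes. Genes with zero counts everywhere are returned flagged with
#' p = 1.
#'
#' @param counts gene x cell count matrix over the cells of both groups.
#' @param group factor/character of length ncol(counts) with exactly two
#'   levels (at least 3 cells each).
#' @param batch optional batch factor (dropped when it has a single level
#'   or is confounded with nothing to estimate).
#' @return data.frame: `gene`, `logFC` (log2), `pvalue`, `fdr`,
#'   `n_groupA`, `n_groupB`, `flagged`.
#' @export
differential_expression <- function(counts, group, batch = NULL) {
  counts <- as.matrix(counts)
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (any(table(group) < 3)) stop("need at least 3 cells per group")
  nonzero <- rowSums(counts) > 0
  y <- edgeR::DGEList(counts = counts[nonzero, , drop = FALSE])
  y <- edgeR::calcNormFactors(y)
  use_batch <- !is.null(batch) && nlevels(factor(batch)) > 1
  design <- if (use_batch) {
    stats::model.matrix(~ factor(batch) + group)
  } else {
    stats::model.matrix(~ group)
  }
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit, coef = ncol(design))
  tab <- lrt$table
  out <- data.frame(gene = rownames(counts),
                    logFC = 0, pvalue = 1, fdr = NA_real_,
                    n_groupA = sum(group == levels(group)[1]),
                    n_groupB = sum(group == levels(group)[2]),
                    flagged = !nonzero, stringsAsFactors = FALSE)
  out$logFC[nonzero] <- tab$logFC
  out$pvalue[nonzero] <- tab$PValue
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  out
}

#' Local-regression dose-response curve for a module score
#'
#' LOESS smoother of module score versus dose with a bootstrap confidence
#' band, evaluated on a fixed dose grid.
#'
#' @param scores,doses per-cell values (at least 20 cells).
#' @param span LOESS span (default 0.75).
#' @param degree local polynomial degree (default 1, which keeps fitted
#'   curves monotone for monotone inputs; quadratic fits overshoot at the
#'   boundaries).
#' @param n_grid evaluation grid size.
#' @param n_boot bootstrap resamples for the band (default 200).
#' @param conf band coverage (default 0.95).
#' @param seed integer seed.
#' @return data.frame `dose`, `fit`, `lower`, `upper`.
#' @export
dose_module_curves <- function(scores, doses, span = 0.75, degree = 1,
                               n_grid = 50, n_boot = 200, conf = 0.95,
                               seed = 1) {
  stopifnot(length(scores) == length(doses))
  if (length(scores) < 20) stop("need at least 20 cells for a dose curve")
  grid <- seq(min(doses), max(doses), length.out = n_grid)
  df <- data.frame(s = scores, d = doses)
  fit0 <- loess(s ~ d, data = df, span = span, degree = degree,
                control = loess.control(surface = "direct"))
  pred <- predict(fit0, data.frame(d = grid))
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, n_grid)
  for (b in seq_len(n_boot)) {
    idx <- sample(nrow(df), replace = TRUE)
    fb <- tryCatch(loess(s ~ d, data = df[idx, ], span = span,
                         degree = degree,
                         control = loess.control(surface = "direct")),
                   error = function(e) NULL)
    if (!is.null(fb)) {
      pb <- tryCatch(predict(fb, data.frame(d = grid)),
                     error = function(e) rep(NA_real_, n_grid))
      if (length(pb) == n_grid) boot[b, ] <- pb
    }
  }
  alpha <- (1 - conf) / 2
  data.frame(dose = grid, fit = pred,
             lower = apply(boot, 2, quantile, alpha, na.rm = TRUE),
             upper = apply(boot, 2, quantile, 1 - alpha, na.rm = TRUE))
}
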