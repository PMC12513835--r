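#' Nearest-neighbour group fractions for combination cells
#'
#' For each cell of the query group (by default the dual-TF group), its
#' `k` nearest neighbours by Euclidean distance in the top PCs of the
#' embedding (self excluded, distance ties broken by cell index) are
#' located among all cells, and the fraction of neighbours from each group
#' recorded; fractions are also averaged over the query cells.
#'
#' @param embedding an `embedding` or a cell x dim score matrix.
#' @param groups group label per cell (e.g. from [assign_pair_groups()]).
#' @param k neighbours (default 5).
#' @param n_pcs PCs used (default 20).
#' @param query_group label of the query group (default `"TF1+TF2"`).
#' @return list with `per_cell` (query cell x group fraction matrix) and
#'   `mean_fractions` (named vector).
#' @export
knn_group_fractions <- function(embedding, groups, k = 5, n_pcs = 20,
                                query_group = "TF1+TF2") {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  scores <- scores[, seq_len(min(n_pcs, ncol(scores))), drop = FALSE]
  stopifnot(length(groups) == nrow(scores))
  n <- nrow(scores)
  if (n < k + 1) stop("need at least k + 1 cells")
  levels <- unique(c("TF1", "TF2", "TF1+TF2", "control", groups))
  query <- which(groups == query_group)
  if (!length(query)) stop("no cells in query group ", query_group)
  nn <- knn_index(scores, k)
  per_cell <- t(vapply(query, function(i) {
    tab <- table(factor(groups[nn[i, ]], levels = levels))
    as.numeric(tab) / k
  }, numeric(length(levels))))
  colnames(per_cell) <- levels
  rownames(per_cell) <- rownames(scores)[query]
  list(per_cell = per_cell, mean_fractions = colMeans(per_cell))
}

#' Summarise a pair's nearest-neighbour fractions for dominance calls
#'
#' Renormalizes the mean neighbour fractions of the dual-TF cells over the
#' two single-TF groups (dual-TF cells are interleaved with their own group,
#' whose share carries no information about which constituent dominates).
#'
#' @param kf result of [knn_group_fractions()].
#' @param tf1,tf2 TF names for the edge table.
#' @return one-row data.frame `tf1`, `tf2`, `frac_tf1`, `frac_tf2`
#'   (fractions sum to 1; `NA` when no single-TF neighbours were seen).
#' @export
pair_dominance_fractions <- function(kf, tf1, tf2) {
  f <- kf$mean_fractions
  tot <- f[["TF1"]] + f[["TF2"]]
  data.frame(tf1 = tf1, tf2 = tf2,
             frac_tf1 = if (tot > 0) f[["TF1"]] / tot else NA_real_,
             frac_tf2 = if (tot > 0) f[["TF2"]] / tot else NA_real_,
             stringsAsFactors = FALSE)
}

#' Directed dominance network over TF pairs
#'
#' For each analyzed pair, an edge `winner -> loser` is drawn when the mean
#' nearest-neighbour fraction of one constituent TF among the dual-TF cells
#' exceeds `dominance_margin` and exceeds the other TF's fraction; edge
#' strength is the fraction difference.
#'
#' @param pair_results data.frame with columns `tf1`, `tf2`, `frac_tf1`,
#'   `frac_tf2` (mean fractions of dual-TF cells nearest to each single-TF
#'   group).
#' @param dominance_margin minimum winning fraction (default 0.5).
#' @return data.frame `winner`, `loser`, `strength` (possibly empty).
#' @export
dominance_network <- function(pair_results, dominance_margin = 0.5) {
  stopifnot(all(c("tf1", "tf2", "frac_tf1", "frac_tf2") %in%
                  names(pair_results)))
  edges <- list()
  for (i in seq_len(nrow(pair_results))) {
    r <- pair_results[i, ]
    if (r$frac_tf1 > dominance_margin && r$frac_tf1 > r$frac_tf2) {
      edges[[length(edges) + 1]] <- data.frame(
        winner = r$tf1, loser = r$tf2, strength = r$frac_tf1 - r$frac_tf2,
        stringsAsFactors = FALSE)
    } else if (r$frac_tf2 > dominance_margin && r$frac_tf2 > r$frac_tf1) {
      edges[[length(edges) + 1]] <- data.frame(
        winner = r$tf2, loser = r$tf1, strength = r$frac_tf2 - r$frac_tf1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(edges)) {
    return(data.frame(winner = character(), loser = character(),
                      strength = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, edges)
}

#' Uniform dose bins with a dedicated zero bin
#'
#' Label 0 for dose exactly 0; labels 1..n for uniform half-open intervals
#' `(0, M/n], (M/n, 2M/n], ...` up to the maximum dose `M`. Doses above `M`
#' are clamped into the top bin with a warning.
#'
#' @param doses non-negative doses.
#' @param max_dose bin range maximum (default `max(doses)`).
#' @param n_bins number of nonzero bins (default 4).
#' @return integer bin labels in `0:n_bins`.
#' @export
dose_bin <- function(doses, max_dose = max(doses), n_bins = 4) {
  stopifnot(all(doses >= 0), max_dose > 0)
  if (any(doses > max_dose)) {
    warning(sum(doses > max_dose), " dose(s) above max_dose clamped")
    doses <- pmin(doses, max_dose)
  }
  ifelse(doses == 0, 0L,
         pmin(n_bins, as.integer(ceiling(doses / (max_dose / n_bins)))))
}

#' Mean nearest-neighbour fractions on a dose-bin grid
#'
#' Averages per-cell group fractions of dual-TF cells over pairs of dose
#' bins (one axis per TF); grid cells with fewer than `min_cells` cells are
#' masked.
#'
#' @param per_cell query cell x group fraction matrix (from
#'   [knn_group_fractions()]).
#' @param bins1,bins2 dose-bin label per query cell (from [dose_bin()]).
#' @param min_cells mask threshold (default 3).
#' @return list of matrices: one mean-fraction grid per group plus `n`
#'   (counts); rows = bins of TF1, columns = bins of TF2.
#' @export
binned_dominance <- function(per_cell, bins1, bins2, min_cells = 3) {
  stopifnot(nrow(per_cell) == length(bins1),
            length(bins1) == length(bins2))
  labs1 <- sort(unique(bins1)); labs2 <- sort(unique(bins2))
  n_mat <- matrix(0, length(labs1), length(labs2),
                  dimnames = list(labs1, labs2))
  grids <- lapply(colnames(per_cell), function(g)
    matrix(NA_real_, length(labs1), length(labs2),
           dimnames = list(labs1, labs2)))
  names(grids) <- colnames(per_cell)
  for (i in seq_along(labs1)) {
    for (j in seq_along(labs2)) {
      idx <- bins1 == labs1[i] & bins2 == labs2[j]
      n_mat[i, j] <- sum(idx)
      if (sum(idx) >= min_cells) {
        for (g in colnames(per_cell)) {
          grids[[g]][i, j] <- mean(per_cell[idx, g])
        }
      }
    }
  }
  c(grids, list(n = n_mat))
}

#' Genes unique to the dual-TF combinatorial state
#'
#' Dual-TF cells whose 5-NN neighbourhood is at least half dual-TF
#' ("qualifying" cells, forming a distinct state) are compared against the
#' union of their nearest matches within the single-TF groups; genes at
#' FDR < `fdr_max` with absolute fold change > `fc_min` define the unique
#' combinatorial signature.
#'
#' @param counts gene x cell counts over all cells of the pair subset.
#' @param embedding embedding of the same cells.
#' @param groups group label per cell.
#' @param batch optional batch per cell.
#' @param k neighbours (default 5).
#' @param n_pcs PCs (default 20).
#' @param same_group_min minimum same-group neighbour fraction to qualify
#'   (default 0.5).
#' @param fdr_max,fc_min significance and fold-change cutoffs (defaults
#'   0.05 and 1.5).
#' @return list with `genes`, `de` (full DE table), `n_qualifying`,
#'   `reason` (non-`NULL` when the result is empty by construction).
#' @export
unique_state_genes <- function(counts, embedding, groups, batch = NULL,
                               k = 5, n_pcs = 20, same_group_min = 0.5,
                               fdr_max = 0.05, fc_min = 1.5) {
  scores <- if (inherits(embedding, "embedding")) embedding$scores else
    as.matrix(embedding)
  scores <- scores[, seq_len(min(n_pcs, ncol(scores))), drop = FALSE]
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(scores), length(groups) == nrow(scores))
  kf <- knn_group_fractions(scores, groups, k = k, n_pcs = n_pcs)
  qual <- rownames(kf$per_cell)[kf$per_cell[, "TF1+TF2"] >= same_group_min]
  if (length(qual) < 3) {
    return(list(genes = character(0), de = NULL, n_qualifying = length(qual),
                reason = "fewer than 3 qualifying dual-TF cells"))
  }
  # nearest matches of qualifying cells within the single-TF groups
  single <- which(groups %in% c("TF1", "TF2"))
  if (length(single) < k) {
    return(list(genes = character(0), de = NULL, n_qualifying = length(qual),
                reason = "too few single-TF cells"))
  }
  qidx <- match(qual, rownames(scores))
  D <- as.matrix(dist(scores))[qidx, single, drop = FALSE]
  comp <- unique(unlist(lapply(seq_along(qidx), function(i) {
    single[order(D[i, ], seq_along(single))[seq_len(k)]]
  })))
  ids <- c(qidx, comp)
  grp <- factor(c(rep("combo", length(qidx)), rep("single", length(comp))),
                levels = c("single", "combo"))
  de <- differential_expression(counts[, ids, drop = FALSE], grp,
                                batch = if (is.null(batch)) NULL else
                                  batch[ids])
  hits <- de$gene[!de$flagged & de$fdr < fdr_max &
                    abs(de$logFC) > log2(fc_min)]
  list(genes = hits, de = de, n_qualifying = length(qual), reason = NULL)
}

#' Dose-binned synergy/antagonism calls
#'
#' Per pair of dose bins, the mean value (gene expression or module score)
#' of dual-TF cells is compared against single-TF cells in the matched
#' marginal bins: synergy when the bootstrap CI of the dual-TF mean lies
#' above the larger single-TF mean, antagonism when below the smaller, else
#' additive; bins without enough cells are indeterminate.
#'
#' @param values per-cell numeric value (aligned with `groups`).
#' @param groups group label per cell.
#' @param bins1,bins2 per-cell dose bins for TF1 and TF2 (from
#'   [dose_bin()]).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf CI coverage (default 0.95).
#' @param min_cells minimum cells per compared group in a bin (default 3).
#' @param seed integer seed.
#' @return data.frame `bin1`, `bin2`, `n`, `combo_mean`, `single1_mean`,
#'   `single2_mean`, `call`.
#' @export
gene_synergy <- function(values, groups, bins1, bins2, n_boot = 1000,
                         conf = 0.95, min_cells = 3, seed = 1) {
  stopifnot(length(values) == length(groups),
            length(bins1) == length(values),
            length(bins2) == length(values))
  set.seed(seed)
  combo <- groups == "TF1+TF2"
  alpha <- (1 - conf) / 2
  rows <- list()
  for (b1 in sort(unique(bins1[combo]))) {
    for (b2 in sort(unique(bins2[combo & bins1 == b1]))) {
      idx <- which(combo & bins1 == b1 & bins2 == b2)
      if (length(idx) < min_cells) next
      v <- values[idx]
      s1 <- values[groups == "TF1" & bins1 == b1]
      s2 <- values[groups == "TF2" & bins2 == b2]
      row <- data.frame(bin1 = b1, bin2 = b2, n = length(idx),
                        combo_mean = mean(v),
                        single1_mean = if (length(s1)) mean(s1) else NA,
                        single2_mean = if (length(s2)) mean(s2) else NA,
                        call = "indeterminate", stringsAsFactors = FALSE)
      if (length(s1) >= min_cells && length(s2) >= min_cells) {
        boot <- vapply(seq_len(n_boot), function(b)
          mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
        ci <- quantile(boot, c(alpha, 1 - alpha), names = FALSE)
        hi <- max(row$single1_mean, row$single2_mean)
        lo <- min(row$single1_mean, row$single2_mean)
        row$call <- if (row$combo_mean > hi && ci[1] > hi) "synergy"
        else if (row$combo_mean < lo && ci[2] < lo) "antagonism"
        else "additive"
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (!length(rows)) {
    return(data.frame(bin1 = integer(), bin2 = integer(), n = integer(),
                      combo_mean = numeric(), single1_mean = numeric(),
                      single2_mean = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
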