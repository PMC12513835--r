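#' Cell-cycle S and G2/M scores
#'
#' Expression-bin-matched module scores ([module_score()]) for the S-phase
#' and G2/M gene programs, computed with a shared seed so both scores use
#' comparable control draws.
#'
#' @param norm normalized gene x cell matrix.
#' @param s_genes,g2m_genes gene sets (non-empty).
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @return data.frame `cell_id`, `s_score`, `g2m_score`.
#' @export
cc_scores <- function(norm, s_genes, g2m_genes, n_bins = 24, n_ctrl = 100,
                      seed = 1) {
  if (!length(s_genes) || !length(g2m_genes)) {
    stop("empty cell-cycle gene list")
  }
  s <- module_score(norm, s_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                    seed = seed)
  g <- module_score(norm, g2m_genes, n_bins = n_bins, n_ctrl = n_ctrl,
                    seed = seed)
  data.frame(cell_id = colnames(norm), s_score = as.numeric(s),
             g2m_score = as.numeric(g), stringsAsFactors = FALSE)
}

#' Raw cell-cycle phase call
#'
#' G1 when both scores are non-positive, otherwise the phase of the larger
#' score (ties resolve to S).
#'
#' @param s_score,g2m_score numeric vectors.
#' @return character vector in `{"G1","S","G2M"}`.
#' @export
assign_phase <- function(s_score, g2m_score) {
  ifelse(s_score <= 0 & g2m_score <= 0, "G1",
         ifelse(s_score >= g2m_score, "S", "G2M"))
}

#' Control-adjusted cell-cycle phase
#'
#' Re-thresholds the phase call at the control population's upper score
#' quantiles: a cell below both control-derived thresholds is G1 even if a
#' score is above zero. Thresholds are clamped at >= 0 so adjustment can
#' only reassign cells toward G1 (controls define the cycling baseline).
#'
#' @param scores data.frame with `s_score`, `g2m_score` (all cells).
#' @param control_scores same columns, control cells only.
#' @param q control quantile (default 0.95).
#' @return character vector of adjusted phases.
#' @export
adjust_phase <- function(scores, control_scores, q = 0.95) {
  thr_s <- max(0, quantile(control_scores$s_score, q, names = FALSE))
  thr_g <- max(0, quantile(control_scores$g2m_score, q, names = FALSE))
  ifelse(scores$s_score <= thr_s & scores$g2m_score <= thr_g, "G1",
         ifelse(scores$s_score >= scores$g2m_score, "S", "G2M"))
}

#' Fisher tests of phase composition per TF
#'
#' For each TF, a Fisher exact test of the 2 x 3 contingency table of
#' adjusted phases (G1/S/G2M) against a reference control group; exact
#' enumeration for small tables, seeded Monte-Carlo p-values for large
#' ones, and Benjamini-Hochberg correction across TFs. Phase columns empty
#' in both groups are collapsed.
#'
#' @param cells data.frame with `assigned_tf` and `phase`.
#' @param ref_group label of the reference group (default `"control"`).
#' @param exact_max largest table total tested by full enumeration
#'   (default 300).
#' @param mc_B Monte-Carlo replicates beyond that (default 1e5).
#' @param seed integer seed for the Monte-Carlo fallback.
#' @return data.frame `tf`, `n`, `pvalue`, `fdr`.
#' @export
phase_fraction_test <- function(cells, ref_group = "control",
                                exact_max = 300, mc_B = 1e5, seed = 1) {
  stopifnot(all(c("assigned_tf", "phase") %in% names(cells)))
  phases <- c("G1", "S", "G2M")
  ref <- table(factor(cells$phase[cells$assigned_tf == ref_group],
                      levels = phases))
  if (sum(ref) < 1) stop("reference group ", ref_group, " is empty")
  tfs <- setdiff(unique(cells$assigned_tf),
                 c(ref_group, "doublet", "unassigned"))
  rows <- lapply(tfs, function(tf) {
    cnt <- table(factor(cells$phase[cells$assigned_tf == tf],
                        levels = phases))
    tab <- rbind(ref = as.integer(ref), tf = as.integer(cnt))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    p <- if (ncol(tab) < 2) 1 else if (sum(tab) <= exact_max) {
      fisher.test(tab)$p.value
    } else {
      set.seed(seed)
      fisher.test(tab, simulate.p.value = TRUE, B = mc_B)$p.value
    }
    data.frame(tf = tf, n = sum(cnt), pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  out
}

#' Kernel density of cell-cycle scores
#'
#' Gaussian-kernel density on a fixed grid, renormalized to integrate to 1
#' over the grid; 2D when a second score vector is given (via
#' [MASS::kde2d()]).
#'
#' @param scores numeric vector (at least 20 cells).
#' @param scores2 optional second score vector for a 2D estimate.
#' @param n_grid grid size per dimension.
#' @param bandwidth bandwidth (default `stats::bw.nrd0` / kde2d default).
#' @return for 1D a data.frame `x`, `density`; for 2D a list `x`, `y`, `z`.
#'   A degenerate (zero-variance) input is flagged via
#'   `attr(,"degenerate")`.
#' @export
score_density <- function(scores, scores2 = NULL, n_grid = 512,
                          bandwidth = NULL) {
  if (length(scores) < 20) stop("need at least 20 cells")
  if (sd(scores) == 0 || (!is.null(scores2) && sd(scores2) == 0)) {
    out <- data.frame(x = unique(scores)[1], density = Inf)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (is.null(scores2)) {
    d <- if (is.null(bandwidth)) density(scores, n = n_grid) else
      density(scores, bw = bandwidth, n = n_grid)
    dx <- diff(d$x[1:2])
    dens <- d$y / (sum(d$y) * dx)               # renormalize on the grid
    out <- data.frame(x = d$x, density = dens)
  } else {
    k <- if (is.null(bandwidth)) MASS::kde2d(scores, scores2, n = n_grid)
    else MASS::kde2d(scores, scores2, h = bandwidth, n = n_grid)
    vol <- sum(k$z) * diff(k$x[1:2]) * diff(k$y[1:2])
    out <- list(x = k$x, y = k$y, z = k$z / vol)
  }
  attr(out, "degenerate") <- FALSE
  out
}

#' Bin a per-cell value by adjusted phase and dose
#'
#' Mean of `value` per (phase, uniform dose bin); bins holding fewer than
#' `min_cells` cells are masked (`NA`), the convention used when displaying
#' differentiation scores over phase and dose.
#'
#' @param cells data.frame with `phase`, `dose` and the value column.
#' @param value_column name of the value column.
#' @param n_dose_bins number of uniform dose bins over `[0, max(dose)]`.
#' @param min_cells mask threshold (default 3).
#' @return list with matrices `mean` and `n` (phase x dose bin).
#' @export
bin_by_dose_phase <- function(cells, value_column, n_dose_bins = 4,
                              min_cells = 3) {
  stopifnot(all(c("phase", "dose", value_column) %in% names(cells)))
  phases <- intersect(c("G1", "S", "G2M"), unique(cells$phase))
  breaks <- seq(0, max(cells$dose), length.out = n_dose_bins + 1)
  bin <- cut(cells$dose, breaks = breaks, include.lowest = TRUE)
  mean_mat <- n_mat <- matrix(NA_real_, length(phases), n_dose_bins,
                              dimnames = list(phases, levels(bin)))
  for (ph in phases) {
    for (b in levels(bin)) {
      v <- cells[[value_column]][cells$phase == ph & bin == b]
      n_mat[ph, b] <- length(v)
      mean_mat[ph, b] <- if (length(v) >= min_cells) mean(v) else NA_real_
    }
  }
  list(mean = mean_mat, n = n_mat)
}
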