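#' Validate a TF-ID barcode library by pairwise Hamming distance
#'
#' Within one experiment only TF-IDs separated by a Hamming distance greater
#' than 2 nucleotides from every other TF-ID are retained for
#' demultiplexing; closer pairs are ambiguous under sequencing error.
#'
#' @param tfids data.frame with columns `tfid` and `barcode`, or a character
#'   vector of barcodes.
#' @param min_distance barcodes at pairwise distance `<= min_distance` are
#'   flagged (default 2).
#' @return list with `flagged_pairs` (data.frame `tfid1`, `tfid2`,
#'   `distance`) and `retained` (TF-IDs in no flagged pair).
#' @export
validate_tfid_library <- function(tfids, min_distance = 2) {
  if (is.character(tfids)) {
    tfids <- data.frame(tfid = if (is.null(names(tfids)))
      tfids else names(tfids), barcode = unname(tfids),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("tfid", "barcode") %in% names(tfids)))
  bc <- tfids$barcode
  if (length(unique(nchar(bc))) > 1) {
    stop("format error: barcode sequences have unequal lengths")
  }
  n <- length(bc)
  chars <- do.call(rbind, strsplit(bc, ""))
  pairs <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- sum(chars[i, ] != chars[j, ])
        if (d <= min_distance) {
          pairs[[length(pairs) + 1]] <- data.frame(
            tfid1 = tfids$tfid[i], tfid2 = tfids$tfid[j], distance = d,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  flagged <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(tfid1 = character(), tfid2 = character(),
               distance = integer(), stringsAsFactors = FALSE)
  bad <- unique(c(flagged$tfid1, flagged$tfid2))
  list(flagged_pairs = flagged, retained = setdiff(tfids$tfid, bad))
}

#' Assign each cell to a TF, control, doublet or unassigned
#'
#' The dominant TF-ID is assigned when its UMI count reaches `min_umi` and
#' the second-to-first UMI ratio is below `ratio_max`; two TF-IDs both at
#' `min_umi` or more with ratio at or above `ratio_max` make a doublet; no
#' TF-ID at `min_umi` leaves the cell unassigned. TF dose is
#' `ln(1 + UMI of the assigned TF-ID)`; doublets and unassigned cells carry
#' no dose.
#'
#' @param tfid a [tfid_counts()].
#' @param min_umi minimum UMI count of the dominant TF-ID (default 2).
#' @param ratio_max maximum second/first UMI ratio for a singlet call
#'   (default 0.2).
#' @param control_tf TF name treated as the control construct; its cells are
#'   labelled `"control"`.
#' @return data.frame (CellTable fragment) with `cell_id`, `assigned_tf`,
#'   `dose`, `umi`, `second_umi`.
#' @export
assign_tf <- function(tfid, min_umi = 2, ratio_max = 0.2,
                      control_tf = "mCherry") {
  stopifnot(inherits(tfid, "tfid_counts"))
  counts <- as.matrix(tfid$counts)
  if (length(counts) == 0) stop("format error: empty TF-ID count matrix")
  n <- ncol(counts)
  assigned <- character(n)
  dose <- rep(NA_real_, n)
  umi <- second <- integer(n)
  tf_of <- setNames(tfid$tfids$tf, tfid$tfids$tfid)
  for (i in seq_len(n)) {
    v <- counts[, i]
    o <- order(v, seq_along(v), decreasing = TRUE)
    c1 <- v[o[1]]; c2 <- if (length(v) > 1) v[o[2]] else 0
    umi[i] <- c1; second[i] <- c2
    if (c1 < min_umi) {
      assigned[i] <- "unassigned"
    } else if (c2 >= min_umi && c2 / c1 >= ratio_max) {
      assigned[i] <- "doublet"
    } else {
      tfn <- tf_of[rownames(counts)[o[1]]]
      assigned[i] <- if (identical(unname(tfn), control_tf)) "control" else
        unname(tfn)
      dose[i] <- log1p(c1)
    }
  }
  data.frame(cell_id = colnames(counts), assigned_tf = assigned, dose = dose,
             umi = umi, second_umi = second, stringsAsFactors = FALSE)
}

#' Quality-control filter on cells
#'
#' Applies the standard per-cell filters of a droplet screen: maximum
#' mitochondrial and ribosomal UMI fractions, minimum protein-coding
#' fraction, a lower-tail outlier rule on log total counts (fail when below
#' median - nmads * MAD) and a minimum number of surviving cells per TF
#' (TFs with fewer than `min_cells_per_tf` passing cells are dropped
#' entirely).
#'
#' @param expr an [expr_matrix()] with gene flags.
#' @param cells data.frame with `cell_id` and `assigned_tf` (e.g. from
#'   [assign_tf()]).
#' @param mito_max,ribo_max,coding_min fraction thresholds (defaults 0.15,
#'   0.60, 0.75).
#' @param nmads number of MADs below the median of log total counts
#'   (default 4, lower tail only).
#' @param min_cells_per_tf minimum passing cells per TF (default 8).
#' @return list with `mask` (logical pass per cell), `flags` (per-rule
#'   logical data.frame, TRUE = failed that rule) and `report` (counts per
#'   rule).
#' @export
qc_filter <- function(expr, cells, mito_max = 0.15, ribo_max = 0.60,
                      coding_min = 0.75, nmads = 4, min_cells_per_tf = 8) {
  stopifnot(inherits(expr, "expr_matrix"))
  g <- expr$genes
  if (!all(c("is_mito", "is_ribo", "is_coding") %in% names(g))) {
    stop("configuration error: gene flags (is_mito/is_ribo/is_coding) missing")
  }
  cells <- cells[match(expr$cells, cells$cell_id), , drop = FALSE]
  total <- Matrix::colSums(expr$counts)
  mito_frac <- Matrix::colSums(expr$counts[g$is_mito, , drop = FALSE]) /
    pmax(total, 1)
  ribo_frac <- Matrix::colSums(expr$counts[g$is_ribo, , drop = FALSE]) /
    pmax(total, 1)
  coding_frac <- Matrix::colSums(expr$counts[g$is_coding, , drop = FALSE]) /
    pmax(total, 1)
  lt <- log(pmax(total, 1))
  lower <- median(lt) - nmads * mad(lt)
  fail_mito <- mito_frac > mito_max
  fail_ribo <- ribo_frac > ribo_max
  fail_coding <- coding_frac < coding_min
  fail_outlier <- lt < lower
  pass <- !(fail_mito | fail_ribo | fail_coding | fail_outlier)

  # drop whole TFs left with too few passing cells
  tf <- cells$assigned_tf
  keep_tf <- names(which(table(tf[pass]) >= min_cells_per_tf))
  fail_min_cells <- pass & !(tf %in% keep_tf) &
    !(tf %in% c("control", "doublet", "unassigned"))
  pass <- pass & !fail_min_cells

  flags <- data.frame(cell_id = expr$cells, fail_mito = fail_mito,
                      fail_ribo = fail_ribo, fail_coding = fail_coding,
                      fail_outlier = fail_outlier,
                      fail_min_cells = fail_min_cells,
                      stringsAsFactors = FALSE)
  report <- list(n_cells = length(pass), n_pass = sum(pass),
                 n_fail_mito = sum(fail_mito), n_fail_ribo = sum(fail_ribo),
                 n_fail_coding = sum(fail_coding),
                 n_fail_outlier = sum(fail_outlier),
                 n_fail_min_cells = sum(fail_min_cells),
                 thresholds = list(mito_max = mito_max, ribo_max = ribo_max,
                                   coding_min = coding_min, nmads = nmads,
                                   min_cells_per_tf = min_cells_per_tf))
  list(mask = setNames(pass, expr$cells), flags = flags, report = report)
}

#' Assign cells to TF-pair dose groups
#'
#' For a combinatorial experiment, each cell falls into exactly one of four
#' groups by a strict UMI rule: `TF1+TF2` (more than `min_umi` UMIs for
#' both), `TF1` or `TF2` (more than `min_umi` for only that TF) or
#' `control` (all other cells).
#'
#' @param tfid a [tfid_counts()].
#' @param tf1,tf2 TF names present in the library.
#' @param min_umi strict UMI threshold (default 4: a cell needs `> 4` UMIs).
#' @return data.frame with `cell_id`, `group`, `umi1`, `umi2`, `dose1`,
#'   `dose2` (doses are `log1p` UMI of each TF).
#' @export
assign_pair_groups <- function(tfid, tf1, tf2, min_umi = 4) {
  stopifnot(inherits(tfid, "tfid_counts"))
  if (identical(tf1, tf2)) stop("configuration error: tf1 == tf2")
  row1 <- tfid$tfids$tfid[tfid$tfids$tf == tf1]
  row2 <- tfid$tfids$tfid[tfid$tfids$tf == tf2]
  if (length(row1) != 1 || length(row2) != 1) {
    stop("configuration error: tf1/tf2 not uniquely present in TF-ID library")
  }
  u1 <- as.numeric(tfid$counts[row1, ])
  u2 <- as.numeric(tfid$counts[row2, ])
  group <- ifelse(u1 > min_umi & u2 > min_umi, "TF1+TF2",
                  ifelse(u1 > min_umi, "TF1",
                         ifelse(u2 > min_umi, "TF2", "control")))
  data.frame(cell_id = tfid$cells, group = group, umi1 = u1, umi2 = u2,
             dose1 = log1p(u1), dose2 = log1p(u2), stringsAsFactors = FALSE)
}
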