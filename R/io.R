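#' Read a Matrix Market count matrix with TSV sidecars
#'
#' Reads the 10x-style triplet: `<prefix>matrix.mtx[.gz]`,
#' `<prefix>features.tsv[.gz]` (row annotation) and
#' `<prefix>barcodes.tsv[.gz]` (column barcodes).
#'
#' @param dir directory holding the triplet.
#' @param prefix optional file-name prefix.
#' @return list with `counts` (sparse matrix), `features` (data.frame) and
#'   `barcodes` (character).
#' @export
read_count_matrix <- function(dir, prefix = "") {
  find <- function(base) {
    for (f in file.path(dir, paste0(prefix, base, c("", ".gz")))) {
      if (file.exists(f)) return(f)
    }
    stop("format error: missing ", base, " in ", dir)
  }
  mtx <- find("matrix.mtx")
  m <- if (grepl("\\.gz$", mtx)) Matrix::readMM(gzfile(mtx)) else
    Matrix::readMM(mtx)
  m <- as(m, "CsparseMatrix")
  read_tsv_noheader <- function(f) {
    lines <- readLines(f)
    if (!length(lines)) {
      return(data.frame(V1 = character(0), stringsAsFactors = FALSE))
    }
    read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
  }
  feat_f <- find("features.tsv")
  features <- read_tsv_noheader(feat_f)
  barcodes <- as.character(read_tsv_noheader(find("barcodes.tsv"))[[1]])
  if (nrow(features) != nrow(m)) {
    stop(sprintf("format error: %d features but %d matrix rows (%s)",
                 nrow(features), nrow(m), feat_f))
  }
  if (length(barcodes) != ncol(m)) {
    stop(sprintf("format error: %d barcodes but %d matrix columns",
                 length(barcodes), ncol(m)))
  }
  rownames(m) <- features[[1]]
  colnames(m) <- barcodes
  list(counts = m, features = features, barcodes = barcodes)
}

#' Write a count matrix as Matrix Market plus TSV sidecars
#'
#' @param counts matrix (coerced to sparse).
#' @param dir output directory (created if needed).
#' @param features data.frame of row annotation (default: row names).
#' @param barcodes column barcodes (default: column names).
#' @param prefix optional file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_count_matrix <- function(counts, dir, features = NULL,
                               barcodes = NULL, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
          "CsparseMatrix")
  if (is.null(features)) features <- data.frame(rownames(m) %||%
                                                  as.character(seq_len(nrow(m))))
  if (is.null(barcodes)) barcodes <- colnames(m) %||%
      as.character(seq_len(ncol(m)))
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "features.tsv",
                                           "barcodes.tsv")))
  Matrix::writeMM(m, paths[1])
  write.table(features, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(barcodes, paths[3])
  invisible(paths)
}

#' Write a simulated experiment to disk
#'
#' Matrix Market + TSV triplets for the expression and TF-ID matrices, the
#' truth table as TSV and the generator configuration as YAML.
#'
#' @param sim a `sim_experiment`.
#' @param dir output directory.
#' @param config optional `sim_config` to echo as YAML.
#' @return invisibly, `dir`.
#' @export
write_sim_experiment <- function(sim, dir, config = NULL) {
  stopifnot(inherits(sim, "sim_experiment"))
  write_count_matrix(sim$expr$counts, file.path(dir, "expression"),
                     features = sim$expr$genes)
  write_count_matrix(sim$tfid$counts, file.path(dir, "tfid"),
                     features = sim$tfid$tfids)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(config)) {
    cfg <- config
    cfg$class_props <- as.list(cfg$class_props)
    if (!is.null(cfg$combos)) cfg$combos <- as.list(cfg$combos)
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), f)
  unname(tools::md5sum(f))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_done <- function(out_dir, stage, hash) {
  f <- file.path(out_dir, sprintf("stage_%s.json", stage))
  if (!file.exists(f)) return(FALSE)
  prov <- tryCatch(jsonlite::read_json(f), error = function(e) NULL)
  identical(prov$config_hash, hash)
}

write_provenance <- function(out_dir, stage, hash, params, seed) {
  jsonlite::write_json(
    list(stage = stage, config_hash = hash, params = params, seed = seed,
         package = "tfdose",
         version = as.character(packageVersion("tfdose"))),
    file.path(out_dir, sprintf("stage_%s.json", stage)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Default pipeline configuration
#'
#' All module parameters with their defaults; any entry can be overridden
#' via `...`. Unknown keys are rejected.
#'
#' @param ... overrides.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_cells_per_tf = 120,
    sim = sim_config(),
    min_umi = 2, ratio_max = 0.2,
    mito_max = 0.15, ribo_max = 0.60, coding_min = 0.75, nmads = 4,
    min_cells_per_tf = 8,
    k_ctrl = 20, n_pcs = 200,
    change_threshold = 0.23,
    resolution = 1.2, k_nn = 20, control_frac = 0.6, min_cells_hetero = 30,
    power_step = 0.25)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("configuration error: unknown keys: ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full synthetic-screen pipeline
#'
#' Executes simulate -> demux -> qc -> change -> fitdose -> power ->
#' hetero -> cellcycle in order, writing one TSV table and one provenance
#' JSON per stage. A rerun with the same configuration skips stages whose
#' outputs already match the configuration hash (delete a stage file to
#' recompute from there).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed

  gt <- simulate_ground_truth(config$sim, seed)
  sim <- simulate_experiment(gt, config$n_cells_per_tf, seed)
  if (!stage_done(out_dir, "simulate", hash)) {
    write_sim_experiment(sim, file.path(out_dir, "simulate"), config$sim)
    write_provenance(out_dir, "simulate", hash,
                     list(n_cells_per_tf = config$n_cells_per_tf), seed)
  }

  cells <- assign_tf(sim$tfid, min_umi = config$min_umi,
                     ratio_max = config$ratio_max,
                     control_tf = config$sim$control_tf)
  cells$batch <- sim$truth$batch[match(cells$cell_id, sim$truth$cell_id)]
  if (!stage_done(out_dir, "demux", hash)) {
    write_tsv(cells, file.path(out_dir, "cells_demux.tsv"))
    write_provenance(out_dir, "demux", hash,
                     list(min_umi = config$min_umi,
                          ratio_max = config$ratio_max), seed)
  }

  qc <- qc_filter(sim$expr, cells, mito_max = config$mito_max,
                  ribo_max = config$ribo_max, coding_min = config$coding_min,
                  nmads = config$nmads,
                  min_cells_per_tf = config$min_cells_per_tf)
  cells$qc_pass <- qc$mask[cells$cell_id]
  if (!stage_done(out_dir, "qc", hash)) {
    write_tsv(qc$flags, file.path(out_dir, "qc_flags.tsv"))
    jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_provenance(out_dir, "qc", hash, qc$report$thresholds, seed)
  }

  keep <- cells$qc_pass & cells$assigned_tf %in%
    c(gt$tf_params$tf, "control")
  kept <- cells[keep, ]
  expr <- normalize_log1p(sim$expr)
  norm <- expr$norm[, kept$cell_id, drop = FALSE]
  res <- regress_control_heterogeneity(norm, kept, k_ctrl = config$k_ctrl)
  emb <- integrate_batches(res, kept$batch, n_pcs = config$n_pcs)
  change <- transcriptomic_change(
    emb, kept$cell_id[kept$assigned_tf == "control"])
  cells$change <- change[cells$cell_id]
  cells$nonfunctional <- label_nonfunctional(cells$change,
                                             config$change_threshold)
  if (!stage_done(out_dir, "change", hash)) {
    write_tsv(cells, file.path(out_dir, "cells_change.tsv"))
    write_provenance(out_dir, "change", hash,
                     list(k_ctrl = config$k_ctrl, n_pcs = config$n_pcs,
                          threshold = config$change_threshold), seed)
  }

  obs <- data.frame(tf = kept$assigned_tf, dose = kept$dose,
                    change = cells$change[match(kept$cell_id,
                                                cells$cell_id)])
  obs <- obs[obs$tf != "control" & is.finite(obs$change), ]
  fits <- classify_tf(fit_logistic_all(obs),
                      capacity_threshold = config$change_threshold)
  if (!stage_done(out_dir, "fitdose", hash)) {
    write_tsv(fits, file.path(out_dir, "dose_response_fits.tsv"))
    write_provenance(out_dir, "fitdose", hash,
                     list(capacity_threshold = config$change_threshold), seed)
  }

  power <- tryCatch(power_analysis(fits, obs, step = config$power_step,
                                   capacity_threshold =
                                     config$change_threshold),
                    error = function(e) NULL)
  if (!is.null(power) && !stage_done(out_dir, "power", hash)) {
    write_tsv(power$p_false_low, file.path(out_dir, "power_false_low.tsv"))
    write_tsv(power$curve, file.path(out_dir, "power_curve.tsv"))
    write_provenance(out_dir, "power", hash,
                     list(step = config$power_step), seed)
  }

  cc <- cc_scores(norm, intersect(gt$s_genes, rownames(norm)),
                  intersect(gt$g2m_genes, rownames(norm)), seed = seed)
  cc$phase <- assign_phase(cc$s_score, cc$g2m_score)
  ctrl_cc <- cc[kept$assigned_tf == "control", ]
  cc$adjusted_phase <- adjust_phase(cc, ctrl_cc)
  cells$phase <- cc$phase[match(cells$cell_id, cc$cell_id)]
  cells$adjusted_phase <- cc$adjusted_phase[match(cells$cell_id, cc$cell_id)]

  hetero_cells <- kept
  hetero_cells$change <- cells$change[match(hetero_cells$cell_id,
                                            cells$cell_id)]
  hetero_cells$adjusted_phase <- cells$adjusted_phase[
    match(hetero_cells$cell_id, cells$cell_id)]
  in_clust <- hetero_cells$adjusted_phase == "G1" &
    (hetero_cells$assigned_tf == "control" |
       !label_nonfunctional(hetero_cells$change, config$change_threshold))
  sub <- hetero_cells[in_clust, ]
  hetero <- NULL
  if (nrow(sub) > config$k_nn + 1) {
    emb_sub <- embed_pca(norm[, sub$cell_id, drop = FALSE],
                         n_pcs = min(50, config$n_pcs))
    assignment <- cluster_cells(emb_sub, resolution = config$resolution,
                                k_nn = config$k_nn, seed = seed)
    flags <- identify_control_clusters(
      assignment, sub$assigned_tf != "control",
      control_frac = config$control_frac)
    hetero <- find_heterogeneous_tfs(assignment, sub, flags,
                                     min_cells = config$min_cells_hetero)
    if (!stage_done(out_dir, "hetero", hash)) {
      write_tsv(merge(assignment, sub[, c("cell_id", "assigned_tf")]),
                file.path(out_dir, "clusters.tsv"))
      write_tsv(hetero, file.path(out_dir, "heterogeneous_tfs.tsv"))
      write_provenance(out_dir, "hetero", hash,
                       list(resolution = config$resolution,
                            control_frac = config$control_frac,
                            min_cells = config$min_cells_hetero), seed)
    }
  }

  cells_for_test <- data.frame(assigned_tf = hetero_cells$assigned_tf,
                               phase = hetero_cells$adjusted_phase)
  phase_tests <- phase_fraction_test(cells_for_test, ref_group = "control",
                                     seed = seed)
  if (!stage_done(out_dir, "cellcycle", hash)) {
    write_tsv(cc, file.path(out_dir, "cellcycle_scores.tsv"))
    write_tsv(phase_tests, file.path(out_dir, "phase_tests.tsv"))
    write_provenance(out_dir, "cellcycle", hash, list(q = 0.95), seed)
  }
  write_tsv(cells, file.path(out_dir, "cell_table.tsv"))

  invisible(list(gt = gt, sim = sim, cells = cells, fits = fits,
                 power = power, hetero = hetero, phase_tests = phase_tests,
                 embedding = emb))
}
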