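# Shared fixture builders: everything is generated in code at test time.

toy_genes <- function(n, mito = integer(0), ribo = integer(0),
                      noncoding = integer(0)) {
  data.frame(gene = sprintf("g%03d", seq_len(n)),
             is_mito = seq_len(n) %in% mito,
             is_ribo = seq_len(n) %in% ribo,
             is_coding = !(seq_len(n) %in% noncoding),
             stringsAsFactors = FALSE)
}

toy_tfid <- function(counts, tfs = rownames(counts)) {
  tfid_counts(counts,
              data.frame(tfid = rownames(counts),
                         barcode = strrep(c("A", "C", "G", "T", "AC",
                                            "GT")[seq_len(nrow(counts))], 6),
                         tf = tfs, stringsAsFactors = FALSE))
}

# small default ground truth for module-level tests
small_gt <- function(seed = 1, n_tfs = 3, ...) {
  simulate_ground_truth(sim_config(n_tfs = n_tfs, n_genes = 700, ...), seed)
}

# run the normalize -> regress -> integrate -> change chain on a simulation
change_chain <- function(sim, n_pcs = 200, g1_only = FALSE) {
  cells <- data.frame(
    cell_id = sim$truth$cell_id,
    assigned_tf = ifelse(sim$truth$tf == "mCherry", "control", sim$truth$tf),
    batch = sim$truth$batch, stringsAsFactors = FALSE)
  if (g1_only) cells <- cells[sim$truth$phase == "G1", ]
  expr <- normalize_log1p(sim$expr)
  res <- regress_control_heterogeneity(expr$norm[, cells$cell_id], cells)
  emb <- integrate_batches(res, cells$batch, n_pcs = n_pcs)
  ch <- transcriptomic_change(emb,
                              cells$cell_id[cells$assigned_tf == "control"])
  list(cells = cells, expr = expr, embedding = emb, change = ch)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
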