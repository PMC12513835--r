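test_that("log-normalization scales cells to a common total", {
  genes <- toy_genes(3)
  counts <- matrix(c(0, 100, 9900,
                     0, 200, 19800), 3, 2,
                   dimnames = list(genes$gene, c("c1", "c2")))
  ex <- normalize_log1p(expr_matrix(counts, genes))
  expect_equal(ex$norm["g001", "c1"], 0)            # zero count stays 0
  expect_equal(ex$norm["g002", "c1"], log(101))     # 100 of 10,000 -> ln(101)
  # scaling invariance: doubled cell has identical normalized vector
  expect_equal(ex$norm[, "c1"], ex$norm[, "c2"])
  # all-zero cell is dropped with a warning
  counts0 <- cbind(counts, c3 = c(0, 0, 0))
  expect_warning(ex0 <- normalize_log1p(expr_matrix(counts0, genes)),
                 "all-zero")
  expect_equal(ncol(ex0$norm), 2)
})

test_that("control-subspace regression obeys the projection identities", {
  set.seed(1)
  n_genes <- 30
  V <- qr.Q(qr(matrix(rnorm(n_genes * 2), n_genes)))  # 2-dim subspace
  ctrl <- V %*% matrix(rnorm(2 * 25, sd = 3), 2)      # controls inside it
  ortho <- qr.Q(qr(cbind(V, rnorm(n_genes))))[, 3]    # orthogonal direction
  tfcell <- ortho * 5
  X <- cbind(ctrl, tfcell)
  colnames(X) <- c(paste0("ctrl", 1:25), "tf1")
  rownames(X) <- paste0("g", seq_len(n_genes))
  cells <- data.frame(cell_id = colnames(X),
                      assigned_tf = c(rep("control", 25), "TFX"),
                      batch = "b1")
  res <- regress_control_heterogeneity(X, cells, k_ctrl = 2)
  # control cells lie exactly in the control subspace -> residual ~ 0
  expect_lt(max(abs(res[, 1:25])), 1e-10)
  # the TF cell is orthogonal to the subspace -> only the centroid is removed
  mu <- rowMeans(X[, 1:25])
  expect_equal(res[, "tf1"], tfcell - mu + (V %*% crossprod(V, mu))[, 1],
               tolerance = 1e-10)
  # k_ctrl = rank of the control data zeroes all control residuals
  res2 <- regress_control_heterogeneity(X, cells, k_ctrl = 25)
  expect_lt(max(abs(res2[, 1:25])), 1e-8)
})

test_that("batch integration reduces to plain PCA for one batch", {
  set.seed(2)
  X <- matrix(rnorm(40 * 25), 40,
              dimnames = list(paste0("g", 1:40), paste0("c", 1:25)))
  emb1 <- integrate_batches(X, batch = rep("b1", 25), n_pcs = 10)
  emb2 <- embed_pca(X, n_pcs = 10)
  # identical embeddings up to component sign
  agree <- abs(colSums(emb1$scores * emb2$scores)) /
    (sqrt(colSums(emb1$scores^2)) * sqrt(colSums(emb2$scores^2)))
  expect_equal(unname(agree), rep(1, 10), tolerance = 1e-8)
  # two identical batches give identical embeddings up to sign
  X2 <- cbind(X, X)
  colnames(X2) <- paste0("c", 1:50)
  emb3 <- integrate_batches(X2, rep(c("b1", "b2"), each = 25), n_pcs = 5)
  expect_equal(abs(emb3$scores[1:25, ]), abs(emb3$scores[26:50, ]),
               ignore_attr = TRUE, tolerance = 1e-8)
  # requested dimension is capped at the rank
  emb4 <- integrate_batches(X[, 1:5], n_pcs = 200)
  expect_lte(emb4$n_pcs, 4)
})

test_that("transcriptomic change matches direct formula evaluation", {
  # 3-cell toy: evaluate the definition by hand
  scores <- rbind(ctrl1 = c(1, 0, 0.5), ctrl2 = c(0.8, 0.2, 0.4),
                  cellA = c(-1, 0.3, 2))
  emb <- structure(list(scores = scores, n_pcs = 3), class = "embedding")
  ch <- transcriptomic_change(emb, c("ctrl1", "ctrl2"))
  centroid <- colMeans(scores[1:2, ])
  raw <- -c(cor(scores[1, ], centroid), cor(scores[2, ], centroid),
            cor(scores[3, ], centroid))
  expected <- raw - mean(raw[1:2])
  expect_equal(unname(ch), unname(expected), tolerance = 1e-12,
               ignore_attr = TRUE)
  # controls average exactly zero
  expect_equal(mean(ch[1:2]), 0, tolerance = 1e-14)
  # a cell equal to the centroid: raw term -1
  emb2 <- structure(list(scores = rbind(scores[1:2, ], cellB = centroid),
                         n_pcs = 3), class = "embedding")
  ch2 <- transcriptomic_change(emb2, c("ctrl1", "ctrl2"))
  expect_equal(unname(ch2["cellB"]), -1 - mean(raw[1:2]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a cell anti-correlated with the centroid has raw term +1 (maximal)
  emb3 <- structure(list(scores = rbind(scores[1:2, ], cellC = -centroid),
                         n_pcs = 3), class = "embedding")
  ch3 <- transcriptomic_change(emb3, c("ctrl1", "ctrl2"))
  expect_equal(unname(ch3["cellC"]), 1 - mean(raw[1:2]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("minimal functional dose inverts a noiseless logistic curve", {
  d <- seq(0, 6, length.out = 601)
  expect_true(is.na(minimal_functional_dose(d, rep(0.1, 601))))
  step <- ifelse(d < 3, 0, 0.5)
  expect_equal(minimal_functional_dose(d, step), 3, tolerance = 0.011)
  # closed-form inversion: a=0, K=0.5, d50=2, s=4 crossing 0.23
  ch <- 0.5 / (1 + exp(-4 * (d - 2)))
  target <- 2 - log(0.5 / 0.23 - 1) / 4
  expect_equal(minimal_functional_dose(d, ch), target, tolerance = 0.011)
  # monotone in the threshold
  set.seed(3)
  noisy <- ch + rnorm(601, sd = 0.02)
  mfds <- vapply(seq(0.05, 0.45, by = 0.05),
                 function(t) minimal_functional_dose(d, noisy, t),
                 numeric(1))
  expect_true(all(diff(mfds) >= 0))
  expect_error(minimal_functional_dose(1:5, 1:5), "at least 10")
})

test_that("housekeeping normalization rescales by the housekeeping mean", {
  expect_equal(unname(normalize_to_housekeeping(c(2, 4, 6), c(1, 3))),
               c(1, 2, 3), ignore_attr = TRUE)
  # hk mean 1 -> identity
  expect_equal(unname(normalize_to_housekeeping(5, c(0.5, 1.5))), 5,
               ignore_attr = TRUE)
  # doubling everything leaves ratios unchanged
  v <- c(2, 4, 6); hk <- c(1, 3)
  expect_equal(unname(normalize_to_housekeeping(2 * v, 2 * hk)),
               unname(normalize_to_housekeeping(v, hk)), ignore_attr = TRUE)
  # missing housekeeping genes reported; fewer than 5 left is an error
  hk_named <- setNames(1:6, paste0("hk", 1:6))
  out <- normalize_to_housekeeping(1, hk_named,
                                   expected = paste0("hk", 1:7))
  expect_equal(attr(out, "missing_hk"), "hk7")
  expect_error(normalize_to_housekeeping(1, hk_named[1:4],
                                         expected = paste0("hk", 1:7)),
               "housekeeping")
})

test_that("physiological comparison uses order-statistic quantiles", {
  set.seed(4)
  vals <- sample(seq(0.1, 2, length.out = 20))
  tab <- data.frame(tf = "TFA",
                    cell_type = rep(c("adipocyte", "neuron"), each = 20),
                    value = c(vals, vals / 10))
  # brute-force order statistics (type 1): ceil(p * n)-th sorted value
  srt <- sort(vals)
  lo <- srt[ceiling(0.05 * 20)]; hi <- srt[ceiling(0.95 * 20)]
  res <- compare_physiological(median(vals), tab, "TFA")
  expect_equal(res$top_cell_type, "adipocyte")
  expect_equal(res$band, c(lo, hi))
  expect_true(res$within_range)
  expect_false(compare_physiological(lo / 2, tab, "TFA")$within_range)
  expect_null(compare_physiological(1, tab, "TFB"))
})

test_that("pairwise similarity agrees with the direct Pearson oracle", {
  set.seed(5)
  S <- matrix(rnorm(6 * 50), 6, dimnames = list(paste0("c", 1:6), NULL))
  emb <- structure(list(scores = S, n_pcs = 50), class = "embedding")
  M <- pairwise_cell_similarity(emb, n_pcs = 50)
  # direct dot-product Pearson oracle
  oracle <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  for (i in 1:6) for (j in 1:6) {
    expect_equal(M[i, j], oracle(S[i, ], S[j, ]), tolerance = 1e-10)
  }
  expect_equal(diag(M), rep(1, 6), ignore_attr = TRUE)
  expect_equal(M, t(M))
  # identical cells correlate at 1
  S2 <- rbind(S, c7 = S[1, ])
  M2 <- pairwise_cell_similarity(structure(list(scores = S2, n_pcs = 50),
                                           class = "embedding"))
  expect_equal(M2["c1", "c7"], 1, tolerance = 1e-12)
})

test_that("module score matches a brute-force bin-matched computation", {
  set.seed(6)
  genes <- toy_genes(10)
  norm <- matrix(abs(rnorm(10 * 8)), 10,
                 dimnames = list(genes$gene, paste0("c", 1:8)))
  gene_set <- c("g002", "g007")
  got <- module_score(norm, gene_set, n_bins = 2, n_ctrl = 100, seed = 9)
  # brute force: 2 bins over the rank of gene means; with n_ctrl >= bin
  # size the control pool is each set gene's whole bin minus itself
  rk <- rank(rowMeans(norm), ties.method = "first")
  bin <- ceiling(rk / 5)
  pool <- unique(unlist(lapply(gene_set, function(g)
    setdiff(names(bin)[bin == bin[g]], g))))
  expected <- colMeans(norm[gene_set, ]) - colMeans(norm[pool, ])
  expect_equal(unname(got), unname(expected), tolerance = 1e-12,
               ignore_attr = TRUE)
  # the full gene set scores itself against its own bins: ~0 signal
  all_score <- module_score(norm, genes$gene, n_bins = 2, seed = 1)
  expect_lt(max(abs(all_score)), 0.5)
  # an unexpressed set against positive controls scores negative
  norm2 <- norm; norm2[c(1, 2), ] <- 0
  sc <- module_score(norm2, c("g001", "g002"), n_bins = 1, seed = 1)
  expect_true(all(sc < 0))
  expect_error(module_score(norm, "g001"), "at least 2")
})

test_that("change metric ranks planted effects and stays null-calibrated", {
  cfg <- sim_config(n_tfs = 1, n_genes = 700,
                    class_props = c(high_sensitive = 0,
                                    high_insensitive = 1, low = 0))
  gt <- simulate_ground_truth(cfg, 11)
  sim <- simulate_experiment(gt, 400, 11, n_control_cells = 150)
  cc <- change_chain(sim, g1_only = TRUE)
  ctrl <- cc$cells$assigned_tf == "control"
  expect_equal(mean(cc$change[ctrl]), 0, tolerance = 1e-12)
  tr <- sim$truth[match(cc$cells$cell_id, sim$truth$cell_id), ]
  expect_gt(cor(cc$change[!ctrl], tr$effect[!ctrl], method = "spearman"),
            0.9)
})

test_that("regression preserves TF signal confined outside the control space", {
  # control variability confined to a known subspace; the planted TF
  # direction must survive regression with high cosine similarity
  set.seed(12)
  n_genes <- 60
  basis <- qr.Q(qr(matrix(rnorm(n_genes * 3), n_genes)))
  Vc <- basis[, 1:2]; v_tf <- basis[, 3]
  ctrl <- Vc %*% matrix(rnorm(2 * 40, sd = 2), 2) +
    matrix(rnorm(n_genes * 40, sd = 0.05), n_genes)
  tfc <- v_tf %*% t(rep(3, 30)) +
    Vc %*% matrix(rnorm(2 * 30, sd = 2), 2) +
    matrix(rnorm(n_genes * 30, sd = 0.05), n_genes)
  X <- cbind(ctrl, tfc)
  colnames(X) <- c(paste0("ctrl", 1:40), paste0("tf", 1:30))
  rownames(X) <- paste0("g", seq_len(n_genes))
  cells <- data.frame(cell_id = colnames(X),
                      assigned_tf = rep(c("control", "TFX"), c(40, 30)),
                      batch = "b1")
  res <- regress_control_heterogeneity(X, cells, k_ctrl = 2)
  recovered <- rowMeans(res[, 41:70]) - rowMeans(res[, 1:40])
  cosine <- sum(recovered * v_tf) / sqrt(sum(recovered^2) * sum(v_tf^2))
  expect_gt(abs(cosine), 0.95)
})
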