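#' Configuration for the synthetic screen generator
#'
#' Defines the study conditions emulated by the generator: the TF cohort and
#' its capacity/sensitivity class mix, module sizes, the per-cell dose
#' distribution (a point mass near zero for uninfected/silenced cells plus a
#' log-normal on UMI counts, reproducing the long-tailed dose spread of a
#' doxycycline-induced screen), negative-binomial count noise, batch effects,
#' doublet and ambient-barcode rates, cell-cycle coupling and TF-pair
#' interactions.
#'
#' @param n_tfs number of TFs (control construct excluded).
#' @param n_genes total genes; must leave room for cell-cycle, housekeeping,
#'   module and QC-flag blocks.
#' @param genes_per_module genes in each TF response module.
#' @param class_props named proportions for classes `high_sensitive`,
#'   `high_insensitive`, `low`; must sum to 1.
#' @param n_batches number of batches (experiments).
#' @param n_branch_tfs number of high-capacity TFs whose response branches
#'   stochastically into two mutually exclusive modules.
#' @param n_nonmono_tfs number of TFs with a non-monotonic (difference of two
#'   logistics) response.
#' @param n_cc_monotonic,n_cc_nonmono number of TFs whose cell-cycle entry is
#'   coupled (monotonically / non-monotonically) to dose.
#' @param doublet_rate fraction of cells carrying two TF-IDs.
#' @param ambient_rate fraction of TF-ID UMIs assigned to wrong cells.
#' @param branch_prob Bernoulli probability of the first branch module.
#' @param dose_zero_prob point mass at zero dose.
#' @param dose_meanlog,dose_sdlog log-normal parameters of the nonzero TF-ID
#'   UMI count (dose = ln(1 + UMI)).
#' @param effect_scale log-fold expression amplitude per unit of plateau
#'   (change units) at saturation.
#' @param baseline_meanlog,baseline_sdlog log-normal prior on gene baseline
#'   means.
#' @param dispersion_meanlog,dispersion_sdlog log-normal prior on NB gene
#'   dispersions.
#' @param batch_sdlog log-normal sd of per-gene per-batch factors.
#' @param cc_amp log-fold activation of S/G2M gene programs in cycling cells.
#' @param control_tf name of the control construct.
#' @param combos optional data.frame with columns `tf1`, `tf2`, `interaction`
#'   (one of `"dominance"`, `"unique_state"`, `"synergy"`, `"antagonism"`),
#'   `dominant` (TF name, dominance only) and `factor` (synergy/antagonism).
#' @param combo_zero_prob per-TF zero-dose probability in combination cells.
#' @param d50_ranges named list of `c(lo, hi)` midpoint ranges per class;
#'   override to position response midpoints relative to the dose range
#'   (e.g. between the pair-grouping UMI threshold and typical doses for
#'   combination designs).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_tfs = 30, n_genes = 2200, genes_per_module = 60,
                       class_props = c(high_sensitive = 1/3,
                                       high_insensitive = 1/3, low = 1/3),
                       n_batches = 2, n_branch_tfs = 0, n_nonmono_tfs = 0,
                       n_cc_monotonic = 0, n_cc_nonmono = 0,
                       doublet_rate = 0.05, ambient_rate = 0.01,
                       branch_prob = 0.5, dose_zero_prob = 0.1,
                       dose_meanlog = 3.2, dose_sdlog = 1.4,
                       effect_scale = 2,
                       baseline_meanlog = log(5), baseline_sdlog = 1,
                       dispersion_meanlog = log(0.1), dispersion_sdlog = 0.3,
                       batch_sdlog = 0.1, cc_amp = 0.8,
                       control_tf = "mCherry", combos = NULL,
                       combo_zero_prob = 0.35,
                       d50_ranges = list(high_sensitive = c(0.8, 1.8),
                                         high_insensitive = c(3.2, 4.2),
                                         low = c(1, 4))) {
  cfg <- as.list(environment())
  if (abs(sum(class_props) - 1) > 1e-8) {
    stop("configuration error: class proportions must sum to 1")
  }
  if (any(class_props < 0)) {
    stop("configuration error: class proportions must be non-negative")
  }
  stopifnot(n_tfs >= 1, genes_per_module >= 2,
            doublet_rate >= 0, doublet_rate <= 1,
            ambient_rate >= 0, ambient_rate <= 1,
            branch_prob >= 0, branch_prob <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# largest-remainder apportionment so exact proportions give exact counts
apportion <- function(props, n) {
  raw <- props * n
  base <- floor(raw + 1e-9)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Draw the ground truth of a synthetic screen
#'
#' Samples per-TF logistic dose-response parameters consistent with the TF's
#' class, allocates disjoint gene modules (including branch and combination
#' modules), batch factors, gene baselines and dispersions. Deterministic for
#' a fixed (config, seed).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `ground_truth`.
#' @export
simulate_ground_truth <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(seed, 0L))
  n_tfs <- config$n_tfs
  classes <- c("high_sensitive", "high_insensitive", "low")
  counts <- apportion(config$class_props[classes], n_tfs)
  class_vec <- rep(classes, counts)

  tf <- sprintf("TF%02d", seq_len(n_tfs))
  a <- runif(n_tfs, -0.02, 0.02)
  K <- d50 <- s <- numeric(n_tfs)
  hs <- class_vec == "high_sensitive"
  hi <- class_vec == "high_insensitive"
  lo <- class_vec == "low"
  dr <- config$d50_ranges
  K[hs] <- runif(sum(hs), 0.5, 1.0)
  d50[hs] <- runif(sum(hs), dr$high_sensitive[1], dr$high_sensitive[2])
  s[hs] <- runif(sum(hs), 1.5, 4)
  K[hi] <- runif(sum(hi), 0.5, 1.0)
  d50[hi] <- runif(sum(hi), dr$high_insensitive[1], dr$high_insensitive[2])
  s[hi] <- runif(sum(hi), 1.5, 3)
  K[lo] <- runif(sum(lo), 0, 0.08)
  d50[lo] <- runif(sum(lo), dr$low[1], dr$low[2])
  s[lo] <- runif(sum(lo), 1, 4)

  shape <- rep("logistic", n_tfs)
  high_idx <- which(!lo)
  nb <- min(config$n_branch_tfs, length(high_idx))
  if (nb > 0) shape[high_idx[seq_len(nb)]] <- "branch"
  free <- setdiff(high_idx, high_idx[seq_len(nb)])
  nn <- min(config$n_nonmono_tfs, length(free))
  if (nn > 0) shape[free[seq_len(nn)]] <- "non_monotonic"

  cc <- rep("none", n_tfs)
  if (config$n_cc_monotonic > 0) {
    cc[seq_len(min(config$n_cc_monotonic, n_tfs))] <- "monotonic"
  }
  if (config$n_cc_nonmono > 0) {
    pool <- which(cc == "none")
    cc[pool[seq_len(min(config$n_cc_nonmono, length(pool)))]] <- "non_monotonic"
  }

  tf_params <- data.frame(tf = tf, class = class_vec, shape = shape,
                          a = a, K = K, d50 = d50, s = s, cc = cc,
                          stringsAsFactors = FALSE)

  # gene layout: cell-cycle programs, housekeeping, TF modules (branch TFs
  # hold two), combination unique modules, then QC-flag genes at the tail
  gpm <- config$genes_per_module
  n_modules <- n_tfs + sum(shape == "branch")
  n_combo <- if (is.null(config$combos)) 0L else
    sum(config$combos$interaction == "unique_state")
  n_flag <- max(20L, ceiling(config$n_genes * 0.12))
  need <- 80 + 13 + (n_modules + n_combo) * gpm + n_flag
  if (config$n_genes < need) {
    stop(sprintf("configuration error: n_genes=%d too small (need >= %d)",
                 config$n_genes, need))
  }
  gene <- sprintf("g%04d", seq_len(config$n_genes))
  s_genes <- gene[1:40]
  g2m_genes <- gene[41:80]
  hk_genes <- gene[81:93]
  cursor <- 94L
  take <- function(k) {
    idx <- cursor:(cursor + k - 1L); cursor <<- cursor + k; gene[idx]
  }
  modules <- setNames(vector("list", n_tfs), tf)
  for (i in seq_len(n_tfs)) {
    modules[[i]] <- list(a = take(gpm),
                         b = if (shape[i] == "branch") take(gpm) else NULL)
  }

  combo_params <- list()
  if (!is.null(config$combos)) {
    for (i in seq_len(nrow(config$combos))) {
      cb <- config$combos[i, ]
      if (!all(c(cb$tf1, cb$tf2) %in% tf)) {
        stop("configuration error: combo names unknown TF")
      }
      key <- paste(cb$tf1, cb$tf2, sep = "+")
      combo_params[[key]] <- list(
        tf1 = cb$tf1, tf2 = cb$tf2, interaction = cb$interaction,
        dominant = if (!is.null(cb$dominant)) cb$dominant else cb$tf1,
        factor = if (!is.null(cb$factor)) cb$factor else 1,
        unique_genes = if (cb$interaction == "unique_state") take(gpm) else NULL)
    }
  }

  # QC flags at the tail of the gene list
  flag_idx <- (config$n_genes - n_flag + 1L):config$n_genes
  nm <- ceiling(n_flag * 0.4)
  is_mito <- is_ribo <- is_coding <- logical(config$n_genes)
  is_coding[] <- TRUE
  is_mito[flag_idx[seq_len(nm)]] <- TRUE
  is_ribo[flag_idx[(nm + 1):(2 * nm)]] <- TRUE
  is_coding[flag_idx[(2 * nm + 1):n_flag]] <- FALSE

  genes <- data.frame(gene = gene, is_mito = is_mito, is_ribo = is_ribo,
                      is_coding = is_coding, stringsAsFactors = FALSE)

  mu <- rlnorm(config$n_genes, config$baseline_meanlog, config$baseline_sdlog)
  phi <- rlnorm(config$n_genes, config$dispersion_meanlog,
                config$dispersion_sdlog)
  batch_factors <- matrix(
    rlnorm(config$n_genes * config$n_batches, 0, config$batch_sdlog),
    nrow = config$n_genes,
    dimnames = list(gene, sprintf("batch%d", seq_len(config$n_batches))))

  structure(list(config = config, tf_params = tf_params, modules = modules,
                 genes = genes, mu = mu, phi = phi,
                 batch_factors = batch_factors,
                 s_genes = s_genes, g2m_genes = g2m_genes,
                 hk_genes = hk_genes, combo_params = combo_params,
                 seed = seed),
            class = "ground_truth")
}

# shape of the dose response on the change scale, in [0, 1]
response_shape <- function(shape, d, d50, s) {
  switch(shape,
         logistic = ,
         branch = logistic_response(d, d50, s),
         non_monotonic = logistic_response(d, d50, s) -
           logistic_response(d, d50 + 2, s),
         stop("unknown response shape: ", shape))
}

# draw TF-ID UMI counts: point mass at 0 plus a rounded log-normal
draw_umis <- function(n, config, zero_prob = config$dose_zero_prob) {
  umi <- ifelse(runif(n) < zero_prob, 0,
                pmax(1, round(rlnorm(n, config$dose_meanlog,
                                     config$dose_sdlog))))
  as.integer(umi)
}

draw_phase <- function(cc, fd) {
  p_cycle <- switch(cc,
                    none = rep(0.3, length(fd)),
                    monotonic = 0.25 + 0.6 * fd,
                    non_monotonic = pmin(0.9, 0.25 + 1.2 * fd))
  u <- runif(length(fd))
  phase <- ifelse(u < p_cycle, ifelse(runif(length(fd)) < 0.5, "S", "G2M"),
                  "G1")
  phase
}

#' Simulate a full synthetic screen experiment
#'
#' Generates, per TF and for the control construct, `n_cells_per_tf` cells
#' with a heavy-tailed TF-ID UMI dose, negative-binomial gene counts whose
#' module means follow the TF's planted response shape, batch factors,
#' cell-cycle programs, TF-ID doublets and ambient barcode UMIs. Control
#' cells receive a dose but zero transcriptomic effect.
#'
#' @param gt a [simulate_ground_truth()] result.
#' @param n_cells_per_tf cells per TF (and for the control).
#' @param seed integer seed.
#' @param n_control_cells number of control cells (default `n_cells_per_tf`).
#' @return object of class `sim_experiment` with elements `expr`
#'   ([expr_matrix()]), `tfid` ([tfid_counts()]) and `truth` (per-cell
#'   data.frame with the planted TF, dose, branch, phase, batch and effect).
#' @export
simulate_experiment <- function(gt, n_cells_per_tf, seed,
                                n_control_cells = n_cells_per_tf) {
  stopifnot(inherits(gt, "ground_truth"), n_cells_per_tf >= 1)
  config <- gt$config
  tfs <- c(gt$tf_params$tf, config$control_tf)
  n_per <- c(rep(n_cells_per_tf, nrow(gt$tf_params)), n_control_cells)
  n_cells <- sum(n_per)
  n_genes <- config$n_genes

  cell_tf <- rep(tfs, n_per)
  cell_id <- sprintf("cell%05d", seq_len(n_cells))

  set.seed(substream_seed(seed, 1L))
  batch <- sample(sprintf("batch%d", seq_len(config$n_batches)), n_cells,
                  replace = TRUE)
  umi <- draw_umis(n_cells, config)
  dose <- log1p(umi)

  is_ctrl <- cell_tf == config$control_tf
  tp <- gt$tf_params[match(cell_tf, gt$tf_params$tf), ]
  fd <- numeric(n_cells)
  fd[!is_ctrl] <- response_shape_vec(tp$shape[!is_ctrl], dose[!is_ctrl],
                                     tp$d50[!is_ctrl], tp$s[!is_ctrl])
  effect_size <- ifelse(is_ctrl, 0, tp$K * fd)

  branch <- rep(NA_character_, n_cells)
  bidx <- which(!is_ctrl & tp$shape == "branch")
  branch[bidx] <- ifelse(runif(length(bidx)) < config$branch_prob, "a", "b")

  phase <- character(n_cells)
  for (ccl in unique(tp$cc[!is_ctrl])) {
    idx <- which(!is_ctrl & tp$cc == ccl)
    phase[idx] <- draw_phase(ccl, fd[idx])
  }
  phase[is_ctrl] <- draw_phase("none", numeric(sum(is_ctrl)))

  # doublets: a second TF-ID with its own dose; its effect is also applied
  is_doublet <- !is_ctrl & runif(n_cells) < config$doublet_rate &
    nrow(gt$tf_params) > 1
  tf2 <- rep(NA_character_, n_cells)
  umi2 <- integer(n_cells)
  didx <- which(is_doublet)
  if (length(didx)) {
    tf2[didx] <- vapply(didx, function(i) {
      pool <- setdiff(gt$tf_params$tf, cell_tf[i])
      pool[sample.int(length(pool), 1)]
    }, character(1))
    umi2[didx] <- draw_umis(length(didx), config, zero_prob = 0)
  }
  dose2 <- log1p(umi2)

  gene_index <- setNames(seq_len(n_genes), gt$genes$gene)
  s_idx <- gene_index[gt$s_genes]
  g2m_idx <- gene_index[gt$g2m_genes]
  batch_i <- match(batch, colnames(gt$batch_factors))

  counts <- matrix(0L, n_genes, n_cells)
  es <- config$effect_scale
  for (i in seq_len(n_cells)) {
    set.seed(substream_seed(seed, 100L + i))
    eff <- numeric(n_genes)
    if (!is_ctrl[i]) {
      mod <- gt$modules[[cell_tf[i]]]
      gset <- if (tp$shape[i] == "branch") {
        if (branch[i] == "a") mod$a else mod$b
      } else mod$a
      eff[gene_index[gset]] <- es * tp$K[i] * fd[i]
      if (is_doublet[i]) {
        tp2 <- gt$tf_params[gt$tf_params$tf == tf2[i], ]
        fd2 <- response_shape(if (tp2$shape == "branch") "logistic" else
          tp2$shape, dose2[i], tp2$d50, tp2$s)
        eff[gene_index[gt$modules[[tf2[i]]]$a]] <-
          eff[gene_index[gt$modules[[tf2[i]]]$a]] + es * tp2$K * fd2
      }
    }
    if (phase[i] == "S") eff[s_idx] <- eff[s_idx] + config$cc_amp
    if (phase[i] == "G2M") eff[g2m_idx] <- eff[g2m_idx] + config$cc_amp
    mu_i <- gt$mu * gt$batch_factors[, batch_i[i]] * exp(eff)
    counts[, i] <- rnbinom(n_genes, mu = mu_i, size = 1 / gt$phi)
  }
  dimnames(counts) <- list(gt$genes$gene, cell_id)

  # TF-ID matrix: own UMIs, doublet UMIs, then ambient contamination
  tfid_names <- tfs
  tc <- matrix(0L, length(tfid_names), n_cells,
               dimnames = list(tfid_names, cell_id))
  tc[cbind(match(cell_tf, tfid_names), seq_len(n_cells))] <- umi
  if (length(didx)) {
    tc[cbind(match(tf2[didx], tfid_names), didx)] <- umi2[didx]
  }
  set.seed(substream_seed(seed, 2L))
  if (config$ambient_rate > 0) {
    lam <- config$ambient_rate * mean(umi)
    n_amb <- rpois(n_cells, lam)
    for (i in which(n_amb > 0)) {
      rows <- sample(length(tfid_names), n_amb[i], replace = TRUE)
      for (r in rows) tc[r, i] <- tc[r, i] + 1L
    }
  }

  barcodes <- make_tfid_barcodes(length(tfid_names))
  tfid <- tfid_counts(tc, data.frame(tfid = tfid_names, barcode = barcodes,
                                     tf = tfid_names,
                                     stringsAsFactors = FALSE), cell_id)
  expr <- expr_matrix(counts, gt$genes, cell_id)
  truth <- data.frame(cell_id = cell_id, tf = cell_tf, batch = batch,
                      umi = umi, dose = dose, branch = branch, phase = phase,
                      is_doublet = is_doublet, tf2 = tf2, umi2 = umi2,
                      effect = effect_size, stringsAsFactors = FALSE)
  structure(list(expr = expr, tfid = tfid, truth = truth, seed = seed),
            class = "sim_experiment")
}

response_shape_vec <- function(shape, d, d50, s) {
  out <- numeric(length(d))
  for (sh in unique(shape)) {
    i <- shape == sh
    out[i] <- response_shape(sh, d[i], d50[i], s[i])
  }
  out
}

# deterministic Hamming-separated barcodes (distance >= 3 by construction:
# distinct base-4 digit strings repeated three times)
make_tfid_barcodes <- function(n, width = 5) {
  stopifnot(n <= 4^width)
  alphabet <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(k) {
    digits <- integer(width)
    for (j in seq_len(width)) { digits[j] <- k %% 4L; k <- k %/% 4L }
    core <- paste(alphabet[digits + 1L], collapse = "")
    paste0(core, core, core)
  }, character(1))
}

#' Simulate dose/change observations with NB-propagated noise
#'
#' Generates per-cell (dose, change) observations directly on the change
#' scale: change = a + K * shape(dose) + noise, where the noise is the
#' centered and scaled mean log1p count of a negative-binomially distributed
#' gene module (centering and scaling use the analytic NB mass function, so
#' the noise is exactly mean-zero with the requested standard deviation).
#' This is the generative counterpart of the logistic dose-response model
#' used for capacity/sensitivity classification.
#'
#' @param gt ground truth.
#' @param n_cells_per_tf cells per TF.
#' @param seed integer seed.
#' @param noise_sd target noise standard deviation on the change scale.
#' @param nb_mu,nb_phi NB mean and dispersion of the module genes carrying
#'   the noise.
#' @return data.frame with columns `tf`, `cell_id`, `dose`, `change`.
#' @export
simulate_dose_response_obs <- function(gt, n_cells_per_tf, seed,
                                       noise_sd = 0.05, nb_mu = 5,
                                       nb_phi = 0.1) {
  stopifnot(inherits(gt, "ground_truth"))
  m <- gt$config$genes_per_module
  # analytic moments of log1p(Y), Y ~ NB(mu, size = 1/phi)
  kmax <- max(50, ceiling(nb_mu + 40 * sqrt(nb_mu + nb_phi * nb_mu^2)))
  k <- 0:kmax
  w <- dnbinom(k, mu = nb_mu, size = 1 / nb_phi)
  w <- w / sum(w)
  e1 <- sum(log1p(k) * w)
  v1 <- sum((log1p(k) - e1)^2 * w)
  sd_mean <- sqrt(v1 / m)

  out <- vector("list", nrow(gt$tf_params))
  for (i in seq_len(nrow(gt$tf_params))) {
    tp <- gt$tf_params[i, ]
    set.seed(substream_seed(seed, 1000L + i))
    umi <- draw_umis(n_cells_per_tf, gt$config)
    dose <- log1p(umi)
    fd <- response_shape(if (tp$shape == "branch") "logistic" else tp$shape,
                         dose, tp$d50, tp$s)
    y <- matrix(rnbinom(n_cells_per_tf * m, mu = nb_mu, size = 1 / nb_phi),
                nrow = m)
    eps <- (colMeans(log1p(y)) - e1) / sd_mean * noise_sd
    out[[i]] <- data.frame(tf = tp$tf,
                           cell_id = sprintf("%s_c%04d", tp$tf,
                                             seq_len(n_cells_per_tf)),
                           dose = dose, change = tp$a + tp$K * fd + eps,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a TF-pair combination experiment
#'
#' Each cell draws independent doses for both TFs (with a point mass at
#' zero, so single-TF and control cells arise naturally); the expression
#' effect is composed according to the pair's planted interaction rule:
#' dominance (the dominant TF's effect applies whenever present),
#' unique_state (both single effects plus a dedicated module once both doses
#' exceed their midpoints), or synergy/antagonism (shared-module effect
#' scaled by the interaction factor when both TFs are present).
#'
#' @param gt ground truth whose `combo_params` contains the pair.
#' @param tf1,tf2 TF names.
#' @param n_cells total cells to simulate.
#' @param seed integer seed.
#' @return a `sim_experiment`; `truth` has per-cell `umi1`, `umi2`, `dose1`,
#'   `dose2` and the active interaction.
#' @export
simulate_combination <- function(gt, tf1, tf2, n_cells, seed) {
  stopifnot(inherits(gt, "ground_truth"))
  key <- paste(tf1, tf2, sep = "+")
  cp <- gt$combo_params[[key]]
  if (is.null(cp)) stop("configuration error: unknown pair ", key)
  config <- gt$config
  p1 <- gt$tf_params[gt$tf_params$tf == tf1, ]
  p2 <- gt$tf_params[gt$tf_params$tf == tf2, ]
  gene_index <- setNames(seq_len(config$n_genes), gt$genes$gene)
  es <- config$effect_scale

  set.seed(substream_seed(seed, 3L))
  cell_id <- sprintf("combo%05d", seq_len(n_cells))
  batch <- sample(sprintf("batch%d", seq_len(config$n_batches)), n_cells,
                  replace = TRUE)
  umi1 <- draw_umis(n_cells, config, zero_prob = config$combo_zero_prob)
  umi2 <- draw_umis(n_cells, config, zero_prob = config$combo_zero_prob)
  d1 <- log1p(umi1); d2 <- log1p(umi2)

  single_eff <- function(p, d) es * p$K * logistic_response(d, p$d50, p$s)
  counts <- matrix(0L, config$n_genes, n_cells)
  batch_i <- match(batch, colnames(gt$batch_factors))
  for (i in seq_len(n_cells)) {
    set.seed(substream_seed(seed, 5000L + i))
    eff <- numeric(config$n_genes)
    if (cp$interaction == "dominance") {
      if ((cp$dominant == tf1 && d1[i] > 0) ||
          (cp$dominant == tf2 && d2[i] > 0)) {
        p <- if (cp$dominant == tf1) p1 else p2
        d <- if (cp$dominant == tf1) d1[i] else d2[i]
        eff[gene_index[gt$modules[[cp$dominant]]$a]] <- single_eff(p, d)
      } else {
        other <- if (cp$dominant == tf1) tf2 else tf1
        p <- if (other == tf1) p1 else p2
        d <- if (other == tf1) d1[i] else d2[i]
        if (d > 0) eff[gene_index[gt$modules[[other]]$a]] <- single_eff(p, d)
      }
    } else if (cp$interaction == "unique_state") {
      if (d1[i] > 0) eff[gene_index[gt$modules[[tf1]]$a]] <- single_eff(p1, d1[i])
      if (d2[i] > 0) eff[gene_index[gt$modules[[tf2]]$a]] <-
          eff[gene_index[gt$modules[[tf2]]$a]] + single_eff(p2, d2[i])
      if (d1[i] > p1$d50 && d2[i] > p2$d50) {
        eff[gene_index[cp$unique_genes]] <- es * 0.8
      }
    } else { # synergy / antagonism on the pair's shared module (tf1's curve)
      shared <- gene_index[gt$modules[[tf1]]$a]
      if (d1[i] > 0 && d2[i] > 0) {
        eff[shared] <- cp$factor * single_eff(p1, max(d1[i], d2[i]))
      } else if (d1[i] > 0) {
        eff[shared] <- single_eff(p1, d1[i])
      } else if (d2[i] > 0) {
        eff[shared] <- single_eff(p1, d2[i])
      }
    }
    mu_i <- gt$mu * gt$batch_factors[, batch_i[i]] * exp(eff)
    counts[, i] <- rnbinom(config$n_genes, mu = mu_i, size = 1 / gt$phi)
  }
  dimnames(counts) <- list(gt$genes$gene, cell_id)

  tfid_names <- c(tf1, tf2, config$control_tf)
  tc <- matrix(0L, 3, n_cells, dimnames = list(tfid_names, cell_id))
  tc[1, ] <- umi1
  tc[2, ] <- umi2
  ctrl <- umi1 == 0 & umi2 == 0
  tc[3, ctrl] <- draw_umis(sum(ctrl), config, zero_prob = 0)
  tfid <- tfid_counts(tc, data.frame(tfid = tfid_names,
                                     barcode = make_tfid_barcodes(3),
                                     tf = tfid_names, stringsAsFactors = FALSE),
                      cell_id)
  truth <- data.frame(cell_id = cell_id, batch = batch, umi1 = umi1,
                      umi2 = umi2, dose1 = d1, dose2 = d2,
                      interaction = cp$interaction, stringsAsFactors = FALSE)
  structure(list(expr = expr_matrix(counts, gt$genes, cell_id), tfid = tfid,
                 truth = truth, seed = seed, pair = key),
            class = "sim_experiment")
}
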