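test_that("class apportionment is exact and invalid proportions are rejected", {
  gt <- simulate_ground_truth(sim_config(n_tfs = 30), seed = 1)
  expect_equal(unname(table(gt$tf_params$class)[c("high_sensitive",
                                                  "high_insensitive",
                                                  "low")]),
               table(factor(rep(c("a", "b", "c"), each = 10))) |>
                 unname() |> as.vector() |> (\(x) as.integer(x))(),
               ignore_attr = TRUE)
  expect_error(sim_config(class_props = c(high_sensitive = 0.5,
                                          high_insensitive = 0.5,
                                          low = 0.5)),
               "proportions")
})

test_that("ground truth is deterministic and respects parameter invariants", {
  cfg <- sim_config(n_tfs = 12, n_genes = 1000)
  gt1 <- simulate_ground_truth(cfg, 7)
  gt2 <- simulate_ground_truth(cfg, 7)
  expect_identical(gt1, gt2)
  expect_true(all(gt1$tf_params$K >= 0))
  expect_true(all(gt1$tf_params$s > 0))
  expect_true(all(gt1$tf_params$d50 >= 0))
  # low-capacity TFs lie below the functional threshold by construction
  low <- gt1$tf_params[gt1$tf_params$class == "low", ]
  expect_true(all(low$a + low$K < 0.23))
  # module gene sets are disjoint
  all_genes <- unlist(lapply(gt1$modules, unlist))
  expect_equal(anyDuplicated(all_genes), 0L)
})

test_that("simulated experiments are reproducible and controls carry no effect", {
  gt <- small_gt(2)
  sim1 <- simulate_experiment(gt, 30, seed = 9)
  sim2 <- simulate_experiment(gt, 30, seed = 9)
  expect_identical(sim1$expr$counts, sim2$expr$counts)
  expect_identical(sim1$tfid$counts, sim2$tfid$counts)
  expect_identical(sim1$truth, sim2$truth)
  ctrl <- sim1$truth$tf == "mCherry"
  expect_true(all(sim1$truth$effect[ctrl] == 0))
  expect_true(any(sim1$truth$dose[ctrl] > 0))   # controls do get a dose
  # truth dose is ln(1 + own pre-ambient UMI)
  expect_equal(sim1$truth$dose, log1p(sim1$truth$umi))
})

test_that("zero doublet rate yields no detectable planted doublets", {
  gt <- small_gt(3, doublet_rate = 0, ambient_rate = 0)
  sim <- simulate_experiment(gt, 40, seed = 4)
  expect_true(all(!sim$truth$is_doublet))
  cells <- assign_tf(sim$tfid)
  expect_true(all(cells$assigned_tf != "doublet"))
})

test_that("logistic module effect hits K/2 at the midpoint (Monte Carlo)", {
  # closed form: at d = d50 the logistic response is exactly 1/2, so the
  # module genes' log-scale effect is effect_scale * K / 2.
  cfg <- sim_config(n_tfs = 1, n_genes = 700,
                    class_props = c(high_sensitive = 1,
                                    high_insensitive = 0, low = 0),
                    dose_zero_prob = 0, n_batches = 1, batch_sdlog = 0,
                    n_cc_monotonic = 0, cc_amp = 0, doublet_rate = 0,
                    ambient_rate = 0)
  gt <- simulate_ground_truth(cfg, 5)
  tp <- gt$tf_params
  sim <- simulate_experiment(gt, 4000, seed = 5, n_control_cells = 10)
  # cells whose dose lands near the midpoint: expected module log-effect
  # averages effect_scale * K * f(d) ~ effect_scale * K / 2 there
  near <- which(abs(sim$truth$dose - tp$d50) < 0.2 &
                  sim$truth$tf == tp$tf)
  expect_gte(length(near), 5)
  mod <- gt$modules[[tp$tf]]$a
  mu_mod <- gt$mu[match(mod, gt$genes$gene)]
  obs <- as.matrix(sim$expr$counts[mod, near, drop = FALSE])
  log_ratio <- log(rowMeans(obs) / mu_mod)
  fbar <- mean(plogis(tp$s * (sim$truth$dose[near] - tp$d50)))
  expect_equal(fbar, 0.5, tolerance = 0.1)
  expect_equal(mean(log_ratio), cfg$effect_scale * tp$K * fbar,
               tolerance = 0.15)
})

test_that("null gene count distribution matches the configured NB", {
  cfg <- sim_config(n_tfs = 1, n_genes = 700, n_batches = 1,
                    batch_sdlog = 0, cc_amp = 0,
                    class_props = c(high_sensitive = 1,
                                    high_insensitive = 0, low = 0))
  gt <- simulate_ground_truth(cfg, 8)
  sim <- simulate_experiment(gt, 5000, seed = 8, n_control_cells = 5000)
  ctrl <- sim$truth$tf == "mCherry"
  g <- "g0500"                                   # a gene outside all modules
  i <- match(g, gt$genes$gene)
  x <- as.numeric(sim$expr$counts[g, ctrl])
  expect_equal(mean(x), gt$mu[i], tolerance = 0.05)
  expect_equal(var(x), gt$mu[i] + gt$phi[i] * gt$mu[i]^2, tolerance = 0.05)
})

test_that("per-TF dose spread covers several ln-UMI units", {
  gt <- small_gt(6)
  sim <- simulate_experiment(gt, 120, seed = 6)
  spread <- tapply(sim$truth$dose, sim$truth$tf, function(d) diff(range(d)))
  expect_true(all(spread >= 3))
})

test_that("NB-propagated dose/change observations follow the planted curve", {
  gt <- small_gt(10)
  obs <- simulate_dose_response_obs(gt, 4000, seed = 3, noise_sd = 0.05)
  tp <- gt$tf_params[1, ]
  d <- obs[obs$tf == tp$tf, ]
  pred <- tp$a + tp$K / (1 + exp(-tp$s * (d$dose - tp$d50)))
  resid <- d$change - pred
  expect_equal(mean(resid), 0, tolerance = 0.005)
  expect_equal(sd(resid), 0.05, tolerance = 0.01)
  # determinism
  obs2 <- simulate_dose_response_obs(gt, 4000, seed = 3, noise_sd = 0.05)
  expect_identical(obs, obs2)
})

test_that("dominance pairs reduce to the dominant TF's transcriptome", {
  cfg <- sim_config(n_tfs = 2, n_genes = 700,
                    class_props = c(high_sensitive = 1,
                                    high_insensitive = 0, low = 0),
                    n_batches = 1, batch_sdlog = 0, cc_amp = 0,
                    combos = data.frame(tf1 = "TF01", tf2 = "TF02",
                                        interaction = "dominance",
                                        dominant = "TF01", factor = 1))
  gt <- simulate_ground_truth(cfg, 2)
  sim <- simulate_combination(gt, "TF01", "TF02", 1500, seed = 2)
  # cells with d2 = 0 and cells with d2 > 0 at matched d1 have the same
  # TF01-module response; TF02's module stays at baseline throughout
  m2 <- gt$modules$TF02$a
  mu2 <- gt$mu[match(m2, gt$genes$gene)]
  with_d2 <- sim$truth$dose2 > 0 & sim$truth$dose1 > 0
  obs2 <- rowMeans(as.matrix(sim$expr$counts[m2, with_d2, drop = FALSE]))
  expect_equal(mean(log(obs2 / mu2)), 0, tolerance = 0.1)
})

test_that("synergy factor scales the shared-module effect multiplicatively", {
  cfg <- sim_config(n_tfs = 2, n_genes = 700,
                    class_props = c(high_sensitive = 1,
                                    high_insensitive = 0, low = 0),
                    n_batches = 1, batch_sdlog = 0, cc_amp = 0,
                    dose_zero_prob = 0, combo_zero_prob = 0,
                    combos = data.frame(tf1 = "TF01", tf2 = "TF02",
                                        interaction = "synergy",
                                        dominant = "TF01", factor = 2))
  gt <- simulate_ground_truth(cfg, 4)
  tp <- gt$tf_params[1, ]
  sim <- simulate_combination(gt, "TF01", "TF02", 1000, seed = 4)
  shared <- gt$modules$TF01$a
  mu_s <- gt$mu[match(shared, gt$genes$gene)]
  # both doses drawn > 0: effect = 2 x single effect at max(d1, d2)
  dmax <- pmax(sim$truth$dose1, sim$truth$dose2)
  high <- dmax > tp$d50 + 2 / tp$s               # near-plateau cells
  obs <- as.matrix(sim$expr$counts[shared, high, drop = FALSE])
  log_ratio <- mean(log(rowMeans(obs) / mu_s))
  single_plateau <- cfg$effect_scale * tp$K *
    mean(1 / (1 + exp(-tp$s * (dmax[high] - tp$d50))))
  expect_equal(log_ratio, 2 * single_plateau, tolerance = 0.05)
})
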