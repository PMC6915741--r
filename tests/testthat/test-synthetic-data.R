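test_that("identical seeds reproduce the dataset exactly; different seeds differ", {
  cfg <- sim_config(n_genes = 200, n_regions = 2, seed = 42,
                    burst_transitions = list(), module_spec = list(),
                    tipping_spec = NULL)
  a <- simulate_lifespan(cfg)
  b <- simulate_lifespan(cfg)
  expect_identical(a$data$expr, b$data$expr)
  expect_identical(a$data$meta, b$data$meta)
  cfg2 <- cfg
  cfg2$seed <- 43L
  c <- simulate_lifespan(cfg2)
  expect_false(identical(a$data$expr, c$data$expr))
})

test_that("ground truth bookkeeping matches the configuration", {
  null_cfg <- sim_config(n_genes = 100, n_regions = 2, seed = 1,
                         burst_transitions = list(), module_spec = list(),
                         tipping_spec = NULL)
  null_truth <- simulate_lifespan(null_cfg)$truth
  expect_identical(nrow(null_truth$planted), 0L)
  expect_true(all(null_truth$module_labels == 0))
  expect_null(null_truth$tipping)

  one_cfg <- sim_config(n_genes = 500, n_regions = 3, seed = 2,
                        burst_transitions = list(
                          list(transition = c(7, 8), n_genes = 100,
                               effect = 1.5, shared_fraction = 0.5)),
                        module_spec = list(), tipping_spec = NULL)
  truth <- simulate_lifespan(one_cfg)$truth
  expect_identical(nrow(truth$planted), 100L)
  expect_true(all(truth$planted$transition == "7-8"))
  expect_identical(sum(truth$planted$regions == "R01;R02;R03"), 50L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(samples_per_cell = 1), "samples_per_cell")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_genes = 100, burst_transitions = list(
    list(transition = c(7, 9), n_genes = 10, effect = 1, shared_fraction = 1))),
    "adjacent")
  expect_error(sim_config(n_genes = 100, burst_transitions = list(
    list(transition = c(7, 8), n_genes = 10, effect = 1, shared_fraction = 2))),
    "shared_fraction")
  expect_error(sim_config(n_genes = 10,
                          burst_transitions = list(
                            list(transition = c(7, 8), n_genes = 100,
                                 effect = 1, shared_fraction = 1))),
               "exceed")
})

test_that("null model: per-gene sample means concentrate around baseline", {
  cfg <- sim_config(n_genes = 300, n_regions = 2, samples_per_cell = 4,
                    noise_sd = 0.5, burst_transitions = list(),
                    module_spec = list(), tipping_spec = NULL, seed = 7)
  sim <- simulate_lifespan(cfg)
  n <- ncol(sim$data$expr)
  dev <- abs(rowMeans(sim$data$expr) - sim$truth$baseline)
  expect_true(all(dev < 4 * 0.5 / sqrt(n)))
})

test_that("module gene pairs are more correlated than background pairs", {
  cfg <- sim_config(n_genes = 300, n_regions = 1, samples_per_cell = 5,
                    burst_transitions = list(), tipping_spec = NULL,
                    module_spec = list(list(size = 50, loading = 0.76)),
                    seed = 3)
  sim <- simulate_lifespan(cfg)
  expect_gt(ncol(sim$data$expr), 50)
  members <- names(sim$truth$module_labels)[sim$truth$module_labels == 1]
  background <- names(sim$truth$module_labels)[sim$truth$module_labels == 0]
  cin <- cor(t(sim$data$expr[members, ]))
  cbg <- cor(t(sim$data$expr[background[1:50], ]))
  expect_gt(mean(cin[upper.tri(cin)]), 0.5)
  expect_lt(abs(mean(cbg[upper.tri(cbg)])), 0.1)
})

test_that("covariate effects propagate into expression when enabled", {
  cfg <- sim_config(n_genes = 100, n_regions = 1, samples_per_cell = 5,
                    covariate_effects = c(pmi = 0.2, rin = 0),
                    burst_transitions = list(), module_spec = list(),
                    tipping_spec = NULL, seed = 5)
  sim <- simulate_lifespan(cfg)
  cors <- apply(sim$data$expr, 1, cor, y = sim$data$meta$pmi)
  expect_gt(median(cors), 0.5)
})

test_that("cell jitter produces an unbalanced design with cells of >= 2", {
  cfg <- sim_config(n_genes = 50, n_regions = 2, samples_per_cell = 4,
                    cell_jitter = 2, burst_transitions = list(),
                    module_spec = list(), tipping_spec = NULL, seed = 9)
  sim <- simulate_lifespan(cfg)
  sizes <- table(sim$data$meta$region, sim$data$meta$stage)
  expect_true(all(sizes >= 2))
  expect_gt(length(unique(as.vector(sizes))), 1)
})

test_that("simulated gene sets reflect planted structure", {
  sim <- small_sim(seed = 4, n_genes = 500,
                   bursts = list(list(transition = c(7, 8), n_genes = 80,
                                      effect = 1.5, shared_fraction = 1),
                                 list(transition = c(10, 11), n_genes = 60,
                                      effect = 1.5, shared_fraction = 1)))
  universe <- rownames(sim$data$expr)
  sets <- simulate_gene_sets(sim$truth, universe, set_size = 50,
                             enriched_fraction = 1, seed = 1)
  expect_true(all(sets$burst1_enriched %in% sim$truth$burst_genes[[1]]))
  expect_true(all(sets$burst2_enriched %in% sim$truth$burst_genes[[2]]))
  # control sets avoid planted genes entirely
  expect_length(intersect(sets$control1, sim$truth$planted$gene), 0)

  # empty truth: only control sets
  null_truth <- small_sim(seed = 5, bursts = list())$truth
  only_ctrl <- simulate_gene_sets(null_truth, universe, set_size = 50, seed = 2)
  expect_identical(names(only_ctrl), "control1")
})

test_that("control-set overlap with a random subset matches hypergeometric expectation", {
  sim <- small_sim(seed = 6, n_genes = 500)
  universe <- rownames(sim$data$expr)
  background <- setdiff(universe, sim$truth$planted$gene)
  set.seed(11)
  probe <- sample(background, 200)
  overlaps <- vapply(1:60, function(s) {
    ctrl <- simulate_gene_sets(sim$truth, universe, set_size = 50, seed = s)$control1
    length(intersect(ctrl, probe))
  }, 0)
  expected <- 50 * 200 / length(background)  # hypergeometric mean
  n_bg <- length(background)
  v <- 50 * (200 / n_bg) * (1 - 200 / n_bg) * (n_bg - 50) / (n_bg - 1)
  expect_lt(abs(mean(overlaps) - expected), 4 * sqrt(v / 60))
})
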