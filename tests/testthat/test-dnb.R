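test_that("stage-wise screens recover planted shifts and exclude the first stage", {
  sim <- small_sim(seed = 51, n_genes = 600, n_regions = 2,
                   bursts = list(list(transition = c(7, 8), n_genes = 50,
                                      effect = 1.5, shared_fraction = 1)))
  cand <- stagewise_candidates(sim$data, alpha = 0.05)
  expect_false("3" %in% names(cand))  # reference stage never tested
  # planted genes shift by 1.5 = 3 * noise SD from stage 8 onward
  planted <- sim$truth$planted$gene
  hits <- intersect(cand[["8"]], planted)
  expect_gte(length(hits) / length(planted), 0.9)
  # before the burst there is nothing to find
  expect_lte(length(cand[["5"]]), 0.05 * 600 + 10)
})

test_that("clustering separates anti-correlated groups and handles singletons", {
  n_samp <- 12
  set.seed(52)
  f <- rnorm(n_samp)
  expr <- rbind(matrix(rep(f, 4), 4, byrow = TRUE) + rnorm(4 * n_samp, 0, 0.05),
                matrix(rep(-f, 4), 4, byrow = TRUE) + rnorm(4 * n_samp, 0, 0.05))
  rownames(expr) <- paste0("g", 1:8)
  colnames(expr) <- paste0("s", 1:n_samp)
  meta <- data.frame(sample_id = colnames(expr), region = "A", stage = 1)
  data <- expression_dataset(expr, meta)
  labels <- cluster_stage_genes(data, 1, rownames(expr), max_clusters = 2)
  expect_identical(length(unique(labels)), 2L)
  expect_equal(adjusted_rand_index(labels, rep(1:2, each = 4)), 1)

  expect_identical(cluster_stage_genes(data, 1, "g1"), c(g1 = 1L))
  tiny <- expression_dataset(expr[, 1:2], meta[1:2, ])
  expect_error(cluster_stage_genes(tiny, 1, rownames(expr)), "fewer than 3")
})

test_that("planted 3-group structure is recovered by the stage clustering", {
  set.seed(53)
  n_samp <- 20
  groups <- rep(1:3, each = 15)
  fs <- matrix(rnorm(3 * n_samp), 3, n_samp)
  expr <- fs[groups, ] + matrix(rnorm(45 * n_samp, 0, 0.3), 45, n_samp)
  rownames(expr) <- paste0("g", 1:45)
  colnames(expr) <- paste0("s", 1:n_samp)
  meta <- data.frame(sample_id = colnames(expr), region = "A", stage = 2)
  data <- expression_dataset(expr, meta)
  labels <- cluster_stage_genes(data, 2, rownames(expr), max_clusters = 3)
  expect_gte(adjusted_rand_index(labels, groups), 0.8)
})

test_that("cluster statistics obey their definition and guards", {
  set.seed(54)
  expr <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  meta <- data.frame(sample_id = colnames(expr), region = "A", stage = 1)
  data <- expression_dataset(expr, meta)
  st <- cluster_statistics(data, 1, paste0("g", 1:5), paste0("g", 6:20))
  # identity CI = sd_avg * pcc_in / pcc_out
  expect_equal(st$ci, st$sd_avg * st$pcc_in / st$pcc_out, tolerance = 1e-12)
  expect_equal(st$sd_avg, mean(apply(expr[1:5, ], 1, sd)), tolerance = 1e-12)
  expect_true(st$pcc_in >= 0 && st$pcc_in <= 1)
  expect_true(st$pcc_out >= 0 && st$pcc_out <= 1)

  single <- cluster_statistics(data, 1, "g1", paste0("g", 2:20))
  expect_identical(single$pcc_in, 1)
  expect_true("singleton_pcc_in" %in% single$flags)

  expect_error(cluster_statistics(data, 1, rownames(expr), character(0)),
               "empty complement")
  expect_error(cluster_statistics(data, 1, "g1", c("g1", "g2")), "overlap")

  # constant complement: correlations undefined -> treated as 0, floored
  expr2 <- expr
  expr2[6:20, ] <- 3
  d2 <- expression_dataset(expr2, meta)
  fl <- cluster_statistics(d2, 1, paste0("g", 1:5), paste0("g", 6:20))
  expect_true("pcc_out_floored" %in% fl$flags)
  expect_identical(fl$pcc_out, 1e-6)
})

test_that("CI scales linearly with the expression scale at a stage", {
  set.seed(55)
  expr <- matrix(rnorm(30 * 12), 30, 12,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:12)))
  meta <- data.frame(sample_id = colnames(expr), region = "A", stage = 4)
  base <- cluster_statistics(expression_dataset(expr, meta), 4,
                             paste0("g", 1:8), paste0("g", 9:30))
  scaled <- cluster_statistics(expression_dataset(expr * 3, meta), 4,
                               paste0("g", 1:8), paste0("g", 9:30))
  expect_equal(scaled$sd_avg, 3 * base$sd_avg, tolerance = 1e-12)
  expect_equal(scaled$pcc_in, base$pcc_in, tolerance = 1e-12)
  expect_equal(scaled$pcc_out, base$pcc_out, tolerance = 1e-12)
  expect_equal(scaled$ci, 3 * base$ci, tolerance = 1e-12)
})

test_that("the planted tipping stage is selected and its CI peaks there", {
  sim <- simulate_lifespan(sim_config(n_genes = 1000, n_regions = 11, seed = 56))
  trace <- dnb_trace(sim$data)
  expect_gte(length(trace$stages), 2)
  sel <- select_dnb(trace)
  expect_identical(sel$stage, sim$truth$tipping$stage)
  expect_false(sel$fallback)
  overlap <- length(intersect(sel$genes, sim$truth$tipping$genes)) /
    length(sim$truth$tipping$genes)
  expect_gte(overlap, 0.8)

  # CI of the planted cluster, measured directly, is maximal at the tipping stage
  planted <- sim$truth$tipping$genes
  rest <- setdiff(rownames(sim$data$expr), planted)
  cis <- vapply(sim$data$stage_order, function(s) {
    cluster_statistics(sim$data, s, planted, rest)$ci
  }, 0)
  expect_identical(sim$data$stage_order[which.max(cis)], sim$truth$tipping$stage)
})

test_that("select_dnb needs two stages and reports the two-stage pair directly", {
  sim <- small_sim(seed = 57, n_genes = 300, n_regions = 2,
                   bursts = list(list(transition = c(7, 8), n_genes = 40,
                                      effect = 1.5, shared_fraction = 1)))
  trace <- dnb_trace(sim$data)
  one_stage <- trace
  one_stage$stages <- trace$stages[1]
  expect_error(select_dnb(one_stage), "at least 2")

  two <- trace
  keep <- as.character(trace$stages[1:2])
  two$stages <- trace$stages[1:2]
  two$members <- trace$members[keep]
  two$stats <- trace$stats[trace$stats$stage %in% trace$stages[1:2], ]
  sel <- select_dnb(two)
  expect_identical(sel$stage, trace$stages[2])
})
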