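test_that("signed adjacency maps correlation extremes as expected", {
  s <- seq(-3, 3, length.out = 7)
  expr <- rbind(a = s, b = s, c = -s, d = c(-3, 3, -3, 3, -2, 2, 0))
  colnames(expr) <- paste0("x", 1:7)
  adj <- signed_adjacency(expr, power = 18)
  expect_equal(adj["a", "b"], 1, tolerance = 1e-12)       # cor +1
  expect_equal(adj["a", "c"], 0, tolerance = 1e-12)       # cor -1
  r_ad <- cor(expr["a", ], expr["d", ])
  expect_equal(adj["a", "d"], ((1 + r_ad) / 2)^18, tolerance = 1e-12)
  expect_equal(unname(diag(adj)), rep(1, 4))
  expect_error(signed_adjacency(rbind(z = rep(1, 7), expr), power = 18),
               "zero-variance")
  # uncorrelated genes land near 0.5^18
  expect_lt(adj["a", "d"], 1e-3)
})

test_that("scale-free fit is exact on a constructed power-law degree vector", {
  # 10 equal-width bins each containing one support point at k = 1..10 with
  # frequency proportional to 1/k: log10(freq) is exactly linear in log10(k)
  k <- rep(1:10, times = 2520 / (1:10))
  r2 <- scale_free_fit_k(k, n_bins = 10)
  expect_equal(as.numeric(r2), 1, tolerance = 1e-6)

  # near-uniform connectivities fit a power law poorly
  set.seed(2)
  expect_lt(abs(scale_free_fit_k(runif(500, 10, 11), n_bins = 10)), 0.9)

  flat <- scale_free_fit_k(rep(3, 50))
  expect_true(is.nan(flat))
  expect_match(attr(flat, "flag"), "degenerate")
  expect_error(scale_free_fit(matrix(1, 2, 2)), "at least 3")
})

test_that("TOM matches the brute-force triple loop and its boundary cases", {
  set.seed(7)
  a <- matrix(runif(400), 20, 20)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  expect_lt(max(abs(topological_overlap(a) - tom_brute(a))), 1e-12)
  expect_true(all(topological_overlap(a) <= 1 + 1e-12))

  pair <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(topological_overlap(pair)[1, 2], 1)
  none <- diag(2)
  expect_equal(topological_overlap(none)[1, 2], 0)

  bad <- a
  bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(topological_overlap(bad), "symmetric")
})

module_expr <- function(seed = 1, sizes = c(100, 100), loading = 0.76,
                        n_noise = 50, n_samples = 120, noise_sd = 0.5) {
  set.seed(seed)
  n <- sum(sizes) + n_noise
  expr <- matrix(rnorm(n * n_samples, 0, noise_sd), n, n_samples)
  labels <- rep(c(seq_along(sizes), 0), c(sizes, n_noise))
  for (m in seq_along(sizes)) {
    f <- rnorm(n_samples)
    expr[labels == m, ] <- expr[labels == m, ] + loading * rep(f, each = sizes[m])
  }
  rownames(expr) <- sprintf("g%04d", 1:n)
  colnames(expr) <- sprintf("s%03d", 1:n_samples)
  list(expr = expr, labels = setNames(labels, rownames(expr)))
}

test_that("planted blocks are recovered as modules; noise stays unassigned", {
  fx <- module_expr(seed = 3)
  tom <- topological_overlap(signed_adjacency(fx$expr))
  labels <- detect_modules(tom, min_module_size = 50)
  expect_gte(adjusted_rand_index(labels, fx$labels), 0.8)
  expect_identical(length(unique(labels[labels > 0])), 2L)

  # pure noise: majority unassigned
  noise <- module_expr(seed = 4, sizes = integer(0), n_noise = 150)
  tom_n <- topological_overlap(signed_adjacency(noise$expr))
  lab_n <- detect_modules(tom_n, min_module_size = 50)
  expect_gt(mean(lab_n == 0), 0.5)

  expect_warning(small <- detect_modules(tom[1:10, 1:10], min_module_size = 50),
                 "min_module_size")
  expect_true(all(small == 0))
})

test_that("module detection is equivariant under gene permutation", {
  fx <- module_expr(seed = 5, sizes = c(60, 60), n_noise = 30)
  tom <- topological_overlap(signed_adjacency(fx$expr))
  lab <- detect_modules(tom, min_module_size = 40)
  set.seed(6)
  perm <- sample(nrow(tom))
  lab_p <- detect_modules(tom[perm, perm], min_module_size = 40)
  expect_equal(adjusted_rand_index(lab[perm], lab_p), 1)
})

test_that("module eigengene matches direct eigendecomposition on a 3-gene fixture", {
  set.seed(9)
  expr <- matrix(rnorm(3 * 40), 3, 40,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:40)))
  expr[2, ] <- 0.8 * expr[1, ] + 0.2 * expr[2, ]
  eg <- module_eigengene(expr, paste0("g", 1:3))
  z <- t(scale(t(expr)))
  ev <- eigen(cov(t(z)) * (40 - 1) / 40)$vectors[, 1]
  ref <- drop(t(z) %*% ev)
  expect_equal(abs(cor(eg, ref)), 1, tolerance = 1e-10)
  expect_gte(cor(eg, colMeans(z)), 0)  # orientation rule
  expect_equal(sd(eg), 1, tolerance = 1e-10)
})

test_that("eigengene conventions: identical genes, sign flips, singletons", {
  prof <- sin(seq_len(30))
  expr <- rbind(a = prof, b = prof, c = prof)
  colnames(expr) <- paste0("s", 1:30)
  eg <- module_eigengene(expr, c("a", "b", "c"))
  expect_equal(abs(cor(eg, prof)), 1, tolerance = 1e-10)
  expect_gt(cor(eg, prof), 0)
  # flipping every gene flips the standardized mean, orientation follows it
  eg_f <- module_eigengene(-expr, c("a", "b", "c"))
  expect_gt(cor(eg_f, scale(-prof)[, 1]), 0)
  single <- module_eigengene(expr, "a")
  expect_equal(unname(single), scale(prof)[, 1], tolerance = 1e-12)
})

orthogonal_factors <- function(n = 40, rho = 0.9, seed = 2) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  z1 <- q[, 1] * sqrt(n - 1)  # unit sample variance, exactly orthogonal
  z2 <- q[, 2] * sqrt(n - 1)
  z1 <- z1 - mean(z1); z2 <- z2 - mean(z2)  # demean (qr columns are not centred)
  z1 <- z1 / sd(z1); z2 <- z2 / sd(z2)
  list(f1 = z1, f2 = rho * z1 + sqrt(1 - rho^2) * z2)
}

test_that("modules merge below the eigengene dissimilarity cutoff and not above", {
  mk <- function(rho) {
    fs <- orthogonal_factors(rho = rho)
    expr <- rbind(matrix(rep(fs$f1, 10), 10, byrow = TRUE),
                  matrix(rep(fs$f2, 10), 10, byrow = TRUE))
    dimnames(expr) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:40))
    labels <- setNames(rep(1:2, each = 10), rownames(expr))
    merge_close_modules(expr, labels, merge_height = 0.15)
  }
  close_rho <- mk(0.95)   # dissimilarity 0.05 < 0.15 -> merged
  expect_identical(length(unique(close_rho[close_rho > 0])), 1L)
  far_rho <- mk(0.5)      # dissimilarity 0.5 >= 0.15 -> kept apart
  expect_identical(length(unique(far_rho[far_rho > 0])), 2L)

  # single module unchanged; procedure idempotent
  fs <- orthogonal_factors()
  expr <- matrix(rep(fs$f1, 5), 5, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
  one <- merge_close_modules(expr, setNames(rep(1L, 5), rownames(expr)))
  expect_true(all(one == 1L))
  twice <- merge_close_modules(expr, one)
  expect_identical(twice, one)
})

test_that("merging is idempotent on multi-module data", {
  fx <- module_expr(seed = 11, sizes = c(40, 40, 40), n_noise = 20)
  once <- merge_close_modules(fx$expr, fx$labels, merge_height = 0.15)
  twice <- merge_close_modules(fx$expr, once, merge_height = 0.15)
  expect_identical(once, twice)
})

test_that("top linked genes rank hubs first", {
  # star: hub connected to all, leaves only to the hub
  n <- 6
  a <- diag(n)
  a[1, 2:n] <- a[2:n, 1] <- 0.9
  dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
  labels <- setNames(rep(1L, n), rownames(a))
  expect_identical(top_linked_genes(a, labels, n = 1), "g1")
  expect_length(top_linked_genes(a, labels, n = n), n)
  expect_error(top_linked_genes(a, labels, n = n + 1), "exceeds")
  # ties broken by gene identifier
  ranked <- top_linked_genes(a, labels, n = n)
  expect_identical(ranked[-1], paste0("g", 2:n))
})

test_that("module-DEG enrichment reuses Fisher/BH and skips label 0", {
  labels <- setNames(c(rep(1L, 30), rep(2L, 30), rep(0L, 40)),
                     sprintf("g%04d", 1:100))
  universe <- names(labels)
  degs <- names(labels)[labels == 1]
  res <- module_deg_enrichment(labels, degs, universe)
  expect_identical(res$module, c(1L, 2L))
  expect_lt(res$q[1], 1e-10)
  expect_gt(res$q[2], 0.5)
  empty <- module_deg_enrichment(setNames(rep(0L, 10), letters[1:10]),
                                 letters[1:2], letters[1:10])
  expect_identical(nrow(empty), 0L)
})
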