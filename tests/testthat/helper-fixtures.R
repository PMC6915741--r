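# Shared fixture builders and independent oracles (kept independent of the
# package's own code paths).

# tiny deterministic dataset: one region, 3 stages x 3 samples, values set
# per gene so sums of squares can be done by hand
tiny_anova_dataset <- function() {
  # gene g1: stage means 1, 2, 4 with within-stage deviations (-0.1, 0, 0.1)
  g1 <- c(0.9, 1.0, 1.1, 1.9, 2.0, 2.1, 3.9, 4.0, 4.1)
  # gene g2: constant everywhere
  g2 <- rep(5, 9)
  # gene g3: pure noise-like fixed values, no stage structure
  g3 <- c(1.2, 0.8, 1.0, 1.1, 0.9, 1.0, 1.0, 1.2, 0.8)
  expr <- rbind(g1 = g1, g2 = g2, g3 = g3)
  colnames(expr) <- paste0("s", 1:9)
  meta <- data.frame(sample_id = paste0("s", 1:9),
                     region = "A",
                     stage = rep(1:3, each = 3))
  expression_dataset(expr, meta)
}

# small simulated dataset for pipeline-level tests
small_sim <- function(seed = 1, n_genes = 400, n_regions = 2,
                      bursts = list(list(transition = c(7, 8), n_genes = 60,
                                         effect = 1.5, shared_fraction = 1)),
                      tipping = NULL, modules = list()) {
  simulate_lifespan(sim_config(
    n_genes = n_genes, n_regions = n_regions, samples_per_cell = 5,
    noise_sd = 0.5, burst_transitions = bursts, module_spec = modules,
    tipping_spec = tipping, seed = seed))
}

# hand-built devdeg_set
devdeg_fixture <- function(sets_by_region, transitions) {
  sets_by_region <- lapply(sets_by_region, function(sets) {
    out <- stats::setNames(vector("list", length(transitions)), transitions)
    for (tr in transitions) out[[tr]] <- if (is.null(sets[[tr]])) character(0) else sets[[tr]]
    out
  })
  structure(sets_by_region, transitions = transitions, class = "devdeg_set")
}

# brute-force step-up BH, independent of stats::p.adjust
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# hypergeometric upper tail by explicit log-binomial summation
hyper_tail_brute <- function(a, K, N, n) {
  hi <- min(K, n)
  if (a > hi) return(0)
  xs <- a:hi
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# studentized-range upper tail by double numerical quadrature
ptukey_quadrature <- function(q, k, df) {
  prange <- function(w) {
    if (w <= 0) return(0)
    k * stats::integrate(function(z) {
      stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
    }, -Inf, Inf, rel.tol = 1e-11)$value
  }
  g <- function(s) {
    exp((df / 2) * log(df) - (df / 2 - 1) * log(2) - lgamma(df / 2) +
          (df - 1) * log(s) - df * s^2 / 2)
  }
  1 - stats::integrate(function(s) {
    vapply(s, function(si) prange(q * si) * g(si), 0)
  }, 0, Inf, rel.tol = 1e-10)$value
}

# triple-loop topological overlap, the slow reference definition
tom_brute <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}
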