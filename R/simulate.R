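#' Configuration for the synthetic lifespan-transcriptome generator
#'
#' Describes a multi-region, multi-stage log2 expression study with planted
#' structure: step-like expression changes concentrated at chosen adjacent
#' stage transitions ("bursts"), correlated gene modules driven by latent
#' factors, nuisance covariates (PMI, RIN), and one gene cluster whose
#' variance and internal correlation spike at a single tipping stage.
#'
#' @param n_genes Number of genes.
#' @param n_regions Number of brain regions.
#' @param stages Ordered integer vector of developmental stages.
#' @param samples_per_cell Samples per region x stage cell (must be >= 2).
#' @param noise_sd Residual log2 noise standard deviation.
#' @param covariate_effects Named numeric vector `c(pmi = , rin = )` of linear
#'   coefficients with which centred PMI/RIN enter every gene. Defaults to 0
#'   so nuisance structure is opt-in.
#' @param burst_transitions List of bursts, each a list with elements
#'   `transition` (adjacent stage pair, e.g. `c(7, 8)`), `n_genes`,
#'   `effect` (log2 step applied at and after the later stage) and
#'   `shared_fraction` (fraction of the burst's genes affected in all regions;
#'   the remainder are each affected in a random proper subset of regions).
#' @param module_spec List of co-expression modules, each a list with `size`
#'   and `loading` (latent-factor loading in log2 units; in-module correlation
#'   is approximately `loading^2 / (loading^2 + noise_sd^2)`).
#' @param tipping_spec `NULL`, or a list with `stage`, `size`, `sd_inflation`,
#'   `corr_inflation` and `mean_shift`. Members receive a `mean_shift` log2
#'   step starting one stage before `stage` (so stage-wise screens against the
#'   first stage can see them) and, at `stage` only, noise inflated by
#'   `sd_inflation` with pairwise correlation `corr_inflation`.
#' @param cell_jitter Non-negative integer; if positive, each region x stage
#'   cell size is jittered uniformly in `samples_per_cell + (-cell_jitter:cell_jitter)`
#'   (floored at 2) to emulate unbalanced staging.
#' @param seed Integer seed; identical configurations produce identical data.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_regions = 11,
                       stages = 3:15,
                       samples_per_cell = 5,
                       noise_sd = 0.5,
                       covariate_effects = c(pmi = 0, rin = 0),
                       burst_transitions = list(
                         list(transition = c(7, 8), n_genes = 250,
                              effect = 1.5, shared_fraction = 0.7),
                         list(transition = c(10, 11), n_genes = 150,
                              effect = 1.5, shared_fraction = 0.7)
                       ),
                       module_spec = list(
                         list(size = 100, loading = 0.76),
                         list(size = 100, loading = 0.76),
                         list(size = 100, loading = 0.76),
                         list(size = 100, loading = 0.76)
                       ),
                       tipping_spec = list(stage = 12, size = 50,
                                           sd_inflation = 3,
                                           corr_inflation = 0.9,
                                           mean_shift = 1.5),
                       cell_jitter = 0,
                       seed = 1) {
  stages <- as.integer(stages)
  stopifnot(n_genes >= 1, n_regions >= 1, length(stages) >= 2,
            !anyDuplicated(stages))
  if (samples_per_cell < 2) {
    stop("samples_per_cell must be >= 2 (within-stage replication is required)")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  ce <- c(pmi = 0, rin = 0)
  ce[names(covariate_effects)] <- covariate_effects
  if (!all(is.finite(ce))) stop("covariate_effects must be finite")
  for (b in burst_transitions) {
    tr <- as.integer(b$transition)
    if (length(tr) != 2 || is.na(match(tr[1], stages)) ||
        match(tr[1], stages) + 1L != match(tr[2], stages)) {
      stop("burst transition must be an adjacent pair within `stages`: ",
           paste(b$transition, collapse = "-"))
    }
    if (b$n_genes < 1) stop("burst n_genes must be positive")
    if (!is.finite(b$effect)) stop("burst effect must be finite")
    if (b$shared_fraction < 0 || b$shared_fraction > 1) {
      stop("shared_fraction must lie in [0, 1]")
    }
  }
  for (m in module_spec) {
    if (m$size < 1) stop("module size must be positive")
    if (!is.finite(m$loading)) stop("module loading must be finite")
  }
  if (!is.null(tipping_spec)) {
    if (is.na(match(tipping_spec$stage, stages)) ||
        match(tipping_spec$stage, stages) < 3L) {
      stop("tipping stage must be in `stages`, with at least two earlier stages")
    }
    if (tipping_spec$size < 2) stop("tipping cluster size must be >= 2")
    stopifnot(tipping_spec$sd_inflation > 0,
              tipping_spec$corr_inflation >= 0, tipping_spec$corr_inflation <= 1)
  }
  n_planted <- sum(vapply(burst_transitions, function(b) b$n_genes, 0)) +
    sum(vapply(module_spec, function(m) m$size, 0)) +
    if (is.null(tipping_spec)) 0L else tipping_spec$size
  if (n_planted > n_genes) {
    stop("planted genes (", n_planted, ") exceed n_genes (", n_genes, ")")
  }
  if (cell_jitter < 0) stop("cell_jitter must be >= 0")
  structure(
    list(n_genes = as.integer(n_genes), n_regions = as.integer(n_regions),
         stages = stages, samples_per_cell = as.integer(samples_per_cell),
         noise_sd = noise_sd, covariate_effects = ce,
         burst_transitions = burst_transitions, module_spec = module_spec,
         tipping_spec = tipping_spec, cell_jitter = as.integer(cell_jitter),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generate a synthetic lifespan expression dataset with known ground truth
#'
#' Baseline log2 means are drawn per gene from Normal(8, 2), the typical
#' range of log-intensity microarray data. Planted burst genes shift their
#' mean by `effect` at and after their transition's later stage (a persistent
#' step, so each planted gene creates an adjacent-stage change at exactly one
#' transition); module genes share a per-sample latent factor; the tipping
#' cluster's noise is inflated and correlated only at the tipping stage.
#' PMI ~ Uniform(5, 30) hours and RIN ~ Uniform(6, 10) are drawn per sample
#' and enter (centred) via `covariate_effects`.
#'
#' @param config A [sim_config()].
#' @return A list with elements `data` (an [expression_dataset()]) and
#'   `truth` (class `ground_truth`): planted burst genes with their transition,
#'   effect and affected regions; module labels (0 = background); the tipping
#'   stage and its gene list; and the seed used.
#' @export
simulate_lifespan <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  stages <- config$stages
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  genes <- sprintf("G%05d", seq_len(config$n_genes))

  # sample layout (optionally unbalanced)
  cells <- expand.grid(region = regions, stage = stages,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_n <- rep(config$samples_per_cell, nrow(cells))
  if (config$cell_jitter > 0) {
    cell_n <- pmax(2L, cell_n + sample(-config$cell_jitter:config$cell_jitter,
                                       nrow(cells), replace = TRUE))
  }
  meta <- data.frame(
    region = rep(cells$region, cell_n),
    stage = rep(cells$stage, cell_n),
    stringsAsFactors = FALSE
  )
  n_samples <- nrow(meta)
  meta$sample_id <- sprintf("S%04d", seq_len(n_samples))
  meta$age <- meta$stage + stats::runif(n_samples, 0, 1)  # nominal, stage-aligned
  meta$pmi <- stats::runif(n_samples, 5, 30)
  meta$rin <- stats::runif(n_samples, 6, 10)
  meta <- meta[, c("sample_id", "region", "stage", "age", "pmi", "rin")]

  # disjoint planted gene allocation
  pool <- sample(config$n_genes)
  take <- function(k) {
    idx <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    idx
  }
  burst_genes <- lapply(config$burst_transitions, function(b) take(b$n_genes))
  module_genes <- lapply(config$module_spec, function(m) take(m$size))
  tipping_genes <- if (is.null(config$tipping_spec)) integer(0) else
    take(config$tipping_spec$size)

  baseline <- stats::rnorm(config$n_genes, 8, 2)
  expr <- matrix(stats::rnorm(config$n_genes * n_samples, 0, config$noise_sd),
                 config$n_genes, n_samples,
                 dimnames = list(genes, meta$sample_id))
  expr <- expr + baseline

  # covariates, centred at their expected values so stage means are unaffected
  ce <- config$covariate_effects
  if (any(ce != 0)) {
    expr <- expr + rep(ce[["pmi"]] * (meta$pmi - 17.5), each = config$n_genes) +
      rep(ce[["rin"]] * (meta$rin - 8), each = config$n_genes)
  }

  # planted step effects
  planted <- data.frame(gene = character(0), transition = character(0),
                        effect = numeric(0), regions = character(0),
                        stringsAsFactors = FALSE)
  stage_rank <- match(meta$stage, stages)
  for (i in seq_along(config$burst_transitions)) {
    b <- config$burst_transitions[[i]]
    idx <- burst_genes[[i]]
    later_rank <- match(as.integer(b$transition)[2], stages)
    n_shared <- round(b$shared_fraction * length(idx))
    shared <- rep(c(TRUE, FALSE), c(n_shared, length(idx) - n_shared))
    reg_sets <- lapply(seq_along(idx), function(j) {
      if (shared[j] || config$n_regions == 1L) return(regions)
      k <- sample.int(config$n_regions - 1L, 1L)
      sort(sample(regions, k))
    })
    for (j in seq_along(idx)) {
      on <- stage_rank >= later_rank & meta$region %in% reg_sets[[j]]
      expr[idx[j], on] <- expr[idx[j], on] + b$effect
    }
    planted <- rbind(planted, data.frame(
      gene = genes[idx],
      transition = paste0(b$transition[1], "-", b$transition[2]),
      effect = b$effect,
      regions = vapply(reg_sets, paste, "", collapse = ";"),
      stringsAsFactors = FALSE
    ))
  }

  # latent-factor co-expression modules
  module_labels <- integer(config$n_genes)
  for (m in seq_along(config$module_spec)) {
    idx <- module_genes[[m]]
    module_labels[idx] <- m
    f <- stats::rnorm(n_samples)
    expr[idx, ] <- expr[idx, ] +
      config$module_spec[[m]]$loading * rep(f, each = length(idx))
  }

  # tipping cluster: mean step from one stage before the tipping point;
  # noise inflated and correlated at the tipping stage only
  tip <- config$tipping_spec
  if (!is.null(tip)) {
    tip_rank <- match(tip$stage, stages)
    on <- stage_rank >= tip_rank - 1L
    expr[tipping_genes, on] <- expr[tipping_genes, on] + tip$mean_shift
    at_tip <- which(stage_rank == tip_rank)
    h <- stats::rnorm(length(at_tip))
    z <- matrix(stats::rnorm(length(tipping_genes) * length(at_tip)),
                length(tipping_genes), length(at_tip))
    new_noise <- tip$sd_inflation * config$noise_sd *
      (sqrt(tip$corr_inflation) * rep(h, each = length(tipping_genes)) +
         sqrt(1 - tip$corr_inflation) * z)
    # replace the original independent noise at the tipping stage
    mu <- baseline[tipping_genes] + tip$mean_shift
    base_part <- matrix(mu, length(tipping_genes), length(at_tip))
    if (any(ce != 0)) {
      base_part <- base_part +
        rep(ce[["pmi"]] * (meta$pmi[at_tip] - 17.5), each = length(tipping_genes)) +
        rep(ce[["rin"]] * (meta$rin[at_tip] - 8), each = length(tipping_genes))
    }
    expr[tipping_genes, at_tip] <- base_part + new_noise
  }

  truth <- structure(
    list(planted = planted,
         burst_genes = lapply(burst_genes, function(i) genes[i]),
         burst_transitions = vapply(config$burst_transitions,
                                    function(b) paste0(b$transition[1], "-",
                                                       b$transition[2]), ""),
         module_labels = stats::setNames(module_labels, genes),
         tipping = if (is.null(tip)) NULL else
           list(stage = as.integer(tip$stage), genes = genes[tipping_genes]),
         baseline = stats::setNames(baseline, genes),
         seed = config$seed),
    class = "ground_truth"
  )
  list(data = expression_dataset(expr, meta, stage_order = stages),
       truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$planted), "planted burst genes at",
      length(unique(x$planted$transition)), "transition(s);",
      sum(x$module_labels > 0), "module genes;",
      if (is.null(x$tipping)) "no tipping cluster" else
        paste0("tipping at stage ", x$tipping$stage,
               " (", length(x$tipping$genes), " genes)"), "\n")
  invisible(x)
}

#' Generate gene-set collections aligned with planted ground truth
#'
#' Emits GMT-serialisable named sets standing in for external functional,
#' disease or cell-type marker lists: one set enriched in first-burst planted
#' genes, one enriched in second-burst genes (when present), and random
#' control sets drawn from non-planted genes.
#'
#' @param truth A `ground_truth` from [simulate_lifespan()].
#' @param universe Character vector of all gene identifiers.
#' @param set_size Size of each emitted set.
#' @param enriched_fraction Fraction of an enriched set drawn from its burst's
#'   planted genes (the remainder is drawn from non-planted genes).
#' @param n_control Number of random control sets.
#' @param seed Integer seed.
#' @return A named list of character vectors with a `description` attribute
#'   per set (a `gene_set_collection`).
#' @export
simulate_gene_sets <- function(truth, universe, set_size = 100,
                               enriched_fraction = 0.8, n_control = 1,
                               seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), set_size >= 1,
            enriched_fraction >= 0, enriched_fraction <= 1)
  set.seed(seed)
  planted_all <- unique(truth$planted$gene)
  background <- setdiff(universe, planted_all)
  sets <- list()
  desc <- character(0)
  for (i in seq_along(truth$burst_genes)) {
    bg <- truth$burst_genes[[i]]
    if (!length(bg)) next
    n_in <- min(round(enriched_fraction * set_size), length(bg))
    n_out <- set_size - n_in
    nm <- paste0("burst", i, "_enriched")
    sets[[nm]] <- sort(c(sample(bg, n_in),
                         sample(background, min(n_out, length(background)))))
    desc[nm] <- paste0("set enriched in planted genes of transition ",
                       truth$burst_transitions[i])
  }
  for (j in seq_len(n_control)) {
    nm <- paste0("control", j)
    sets[[nm]] <- sort(sample(background, min(set_size, length(background))))
    desc[nm] <- "random control set from non-planted genes"
  }
  for (nm in names(sets)) attr(sets[[nm]], "description") <- desc[[nm]]
  class(sets) <- "gene_set_collection"
  sets
}
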