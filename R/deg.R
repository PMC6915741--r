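#' Per-gene stage ANOVA with optional technical covariates
#'
#' For every gene in one region, fits a linear model of log2 expression on
#' developmental stage (categorical) plus optional covariates (e.g. PMI and
#' RIN) and returns the partial F test for the stage factor. With no
#' covariates this is one-way ANOVA. All genes share the design, so residual
#' sums of squares are obtained from two QR decompositions rather than
#' per-gene `lm` fits.
#'
#' @param data An [expression_dataset()].
#' @param region Region label to analyse.
#' @param covariates Character vector of metadata columns to adjust for
#'   (subset of the numeric metadata columns, e.g. `c("pmi", "rin")`).
#' @return Data frame with one row per gene: `gene`, `F`, `p`, `df1`, `df2`,
#'   and `degenerate` (TRUE for zero-variance genes, which get `F = 0`,
#'   `p = 1` by convention). Unbounded F statistics (zero residual variance
#'   with differing stage means) are guarded at 1e12.
#' @export
fit_stage_anova <- function(data, region, covariates = character(0)) {
  stopifnot(inherits(data, "expression_dataset"))
  keep <- data$meta$region == region
  if (!any(keep)) stop("region not present in dataset: ", region)
  meta <- data$meta[keep, , drop = FALSE]
  tab <- table(meta$stage)
  if (length(tab) < 2) stop("region ", region, " has fewer than 2 stages")
  small <- names(tab)[tab < 2]
  if (length(small)) {
    stop("stage(s) with fewer than 2 samples in region ", region, ": ",
         paste(small, collapse = ", "))
  }
  miss <- setdiff(covariates, names(meta))
  if (length(miss)) stop("covariate column(s) absent: ", paste(miss, collapse = ", "))

  Y <- t(data$expr[, meta$sample_id, drop = FALSE])
  stage <- factor(meta$stage, levels = data$stage_order[data$stage_order %in% meta$stage])
  if (length(covariates)) {
    X0 <- stats::model.matrix(
      stats::reformulate(covariates),
      data = meta)
    X1 <- cbind(X0, stats::model.matrix(~ stage)[, -1, drop = FALSE])
  } else {
    X0 <- matrix(1, nrow(Y), 1)
    X1 <- stats::model.matrix(~ stage)
  }
  q0 <- qr(X0)
  q1 <- qr(X1)
  rss0 <- colSums(qr.resid(q0, Y)^2)
  rss1 <- colSums(qr.resid(q1, Y)^2)
  df1 <- q1$rank - q0$rank
  df2 <- nrow(Y) - q1$rank
  if (df2 < 1) stop("no residual degrees of freedom in region ", region)

  totvar <- colSums(scale(Y, scale = FALSE)^2)
  degenerate <- totvar <= .Machine$double.eps * nrow(Y)
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  # zero residual variance but real stage differences: guard F to a large value
  exploded <- !degenerate & rss1 <= .Machine$double.eps * pmax(rss0, 1)
  Fstat[exploded] <- 1e12
  Fstat[Fstat < 0] <- 0  # numerical noise
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  Fstat[degenerate] <- 0
  p[degenerate] <- 1
  data.frame(gene = rownames(data$expr), F = unname(Fstat), p = unname(p),
             df1 = df1, df2 = df2, degenerate = unname(degenerate),
             stringsAsFactors = FALSE)
}

#' Covariate-free stage means of one region
#'
#' @param data An [expression_dataset()].
#' @param region Region label.
#' @return Numeric matrix, genes x stages (columns named by stage), of
#'   per-stage mean log2 expression.
#' @export
stage_means <- function(data, region) {
  stopifnot(inherits(data, "expression_dataset"))
  keep <- data$meta$region == region
  if (!any(keep)) stop("region not present in dataset: ", region)
  meta <- data$meta[keep, , drop = FALSE]
  stages <- data$stage_order[data$stage_order %in% meta$stage]
  X <- data$expr[, meta$sample_id, drop = FALSE]
  out <- vapply(stages, function(s) {
    rowMeans(X[, meta$stage == s, drop = FALSE])
  }, numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(rownames(X), as.character(stages)))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: sort p ascending, take running minima of `p_(j) * m / j` from
#' the largest rank down, clip at 1, and return in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA`/`NaN` are rejected.
#' @return Vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("bh_adjust: p-values contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("bh_adjust: p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call temporal DEGs from per-region ANOVA results
#'
#' A gene is a temporal DEG in a region when its BH-adjusted stage-ANOVA
#' q-value falls below `q_threshold` and its expression range across stage
#' means (max minus min, log2 scale) reaches `log2_fc_threshold`; the default
#' thresholds encode FDR Q < 0.01 with at least a 2-fold change. BH is
#' applied within each region across genes (one family per region).
#'
#' @param anova_by_region Named list (by region) of data frames from
#'   [fit_stage_anova()].
#' @param means_by_region Named list (by region) of stage-mean matrices from
#'   [stage_means()], aligned with the ANOVA gene order.
#' @param q_threshold FDR threshold (exclusive: `q < q_threshold`).
#' @param log2_fc_threshold Log2 range threshold (inclusive: `range >= threshold`).
#' @return Long data frame: `gene`, `region`, `F`, `p`, `q`, `log2_range`,
#'   `is_temporal_deg`.
#' @export
call_temporal_degs <- function(anova_by_region, means_by_region,
                               q_threshold = 0.01, log2_fc_threshold = 1) {
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold > 1) {
    stop("q_threshold must lie in (0, 1]")
  }
  if (!is.numeric(log2_fc_threshold) || log2_fc_threshold < 0) {
    stop("log2_fc_threshold must be non-negative")
  }
  stopifnot(identical(sort(names(anova_by_region)), sort(names(means_by_region))))
  out <- lapply(names(anova_by_region), function(r) {
    a <- anova_by_region[[r]]
    m <- means_by_region[[r]]
    stopifnot(identical(a$gene, rownames(m)))
    rng <- apply(m, 1, max) - apply(m, 1, min)
    q <- bh_adjust(a$p)
    data.frame(gene = a$gene, region = r, F = a$F, p = a$p, q = q,
               log2_range = unname(rng),
               is_temporal_deg = q < q_threshold & rng >= log2_fc_threshold,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("temporal_deg_table", "data.frame")
  res
}

#' Temporal DEG table for all regions of a dataset
#'
#' Convenience wrapper running [fit_stage_anova()] and [stage_means()] in
#' every region and calling [call_temporal_degs()].
#'
#' @inheritParams fit_stage_anova
#' @inheritParams call_temporal_degs
#' @param regions Regions to analyse (default: all in the dataset).
#' @return A `temporal_deg_table` (see [call_temporal_degs()]), with the
#'   stage-mean matrices attached as attribute `stage_means`.
#' @export
temporal_deg_table <- function(data, covariates = character(0),
                               regions = NULL,
                               q_threshold = 0.01, log2_fc_threshold = 1) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(regions)) regions <- sort(unique(data$meta$region))
  anova_by_region <- lapply(stats::setNames(regions, regions), function(r) {
    fit_stage_anova(data, r, covariates = covariates)
  })
  means_by_region <- lapply(stats::setNames(regions, regions), function(r) {
    stage_means(data, r)
  })
  res <- call_temporal_degs(anova_by_region, means_by_region,
                            q_threshold = q_threshold,
                            log2_fc_threshold = log2_fc_threshold)
  attr(res, "stage_means") <- means_by_region
  res
}

#' Tukey HSD over all stage pairs of one region
#'
#' For every unordered pair of stages, reports the difference of covariate-free
#' stage means (later minus earlier stage) and, optionally, the Tukey-adjusted
#' p-value from the studentized-range distribution with the pooled
#' within-stage variance. Unequal group sizes use the Tukey-Kramer standard
#' error `sqrt(MSE/2 * (1/n_a + 1/n_b))`.
#'
#' @param data An [expression_dataset()].
#' @param region Region label.
#' @param genes Optional character vector restricting the genes analysed
#'   (p-value evaluation over the studentized-range distribution is costly,
#'   so restricting to e.g. temporal DEGs is often appropriate).
#' @param compute_p If `FALSE`, `p_adj` is `NA` and only differences and
#'   q-statistics are returned.
#' @return A `tukey_result` data frame: `gene`, `stage_a`, `stage_b`
#'   (`stage_a` earlier in the stage order), `diff` (mean of `stage_b` minus
#'   mean of `stage_a`), `q_stat`, `p_adj`, `degenerate` (zero pooled
#'   variance: `p_adj` is 0 where means differ, 1 otherwise). Attributes
#'   `nmeans` and `df` carry the studentized-range parameters.
#' @export
tukey_hsd <- function(data, region, genes = NULL, compute_p = TRUE) {
  stopifnot(inherits(data, "expression_dataset"))
  keep <- data$meta$region == region
  if (!any(keep)) stop("region not present in dataset: ", region)
  meta <- data$meta[keep, , drop = FALSE]
  tab <- table(meta$stage)
  if (length(tab) < 2) stop("region ", region, " has fewer than 2 stages")
  if (any(tab < 2)) {
    stop("stage(s) with fewer than 2 samples in region ", region, ": ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  X <- data$expr[, meta$sample_id, drop = FALSE]
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(X))
    if (length(miss)) stop("unknown gene(s): ", paste(utils::head(miss, 5), collapse = ", "))
    X <- X[genes, , drop = FALSE]
  }
  stages <- data$stage_order[data$stage_order %in% meta$stage]
  k <- length(stages)
  n_by_stage <- as.integer(table(factor(meta$stage, levels = stages)))
  means <- vapply(stages, function(s) rowMeans(X[, meta$stage == s, drop = FALSE]),
                  numeric(nrow(X)))
  means <- matrix(means, nrow = nrow(X))
  # pooled within-stage variance (one-way MSE)
  ss_within <- numeric(nrow(X))
  for (i in seq_along(stages)) {
    sub <- X[, meta$stage == stages[i], drop = FALSE]
    ss_within <- ss_within + rowSums((sub - means[, i])^2)
  }
  df <- ncol(X) - k
  mse <- ss_within / df
  degen <- mse <= .Machine$double.eps

  pairs <- utils::combn(seq_len(k), 2)
  res <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- means[, b] - means[, a]
    se <- sqrt(mse / 2 * (1 / n_by_stage[a] + 1 / n_by_stage[b]))
    qst <- abs(d) / se
    qst[degen] <- Inf
    p <- rep(NA_real_, length(d))
    if (compute_p) {
      ok <- !degen
      p[ok] <- stats::ptukey(qst[ok], nmeans = k, df = df, lower.tail = FALSE)
      p[degen] <- ifelse(abs(d[degen]) > 0, 0, 1)
    }
    res[[j]] <- data.frame(gene = rownames(X),
                           stage_a = stages[a], stage_b = stages[b],
                           diff = unname(d), q_stat = unname(qst),
                           p_adj = unname(p), degenerate = unname(degen),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "nmeans") <- k
  attr(out, "df") <- df
  attr(out, "region") <- region
  class(out) <- c("tukey_result", "data.frame")
  out
}

#' Inter-stage DEG combination counts (waterfall surface)
#'
#' Counts, per region and stage pair, the temporal DEGs whose Tukey-adjusted
#' p-value falls below `alpha`. On lifespan brain data this surface shows the
#' "waterfall" pattern: large counts among fetal stage pairs, dropping sharply
#' after birth.
#'
#' @param tukey_by_region Named list (by region) of [tukey_hsd()] results with
#'   p-values computed.
#' @param degs A `temporal_deg_table` covering the same regions.
#' @param alpha Tukey significance threshold.
#' @return Numeric matrix, stage pairs (rows, named `"a-b"`) x regions.
#' @export
interstage_combination_counts <- function(tukey_by_region, degs, alpha = 0.05) {
  stopifnot(inherits(degs, "data.frame"))
  regions <- names(tukey_by_region)
  pair_names <- NULL
  cols <- lapply(regions, function(r) {
    tk <- tukey_by_region[[r]]
    if (anyNA(tk$p_adj)) stop("Tukey p-values missing for region ", r,
                              " (rerun tukey_hsd with compute_p = TRUE)")
    deg_genes <- degs$gene[degs$region == r & degs$is_temporal_deg]
    extra <- setdiff(unique(tk$gene), degs$gene[degs$region == r])
    if (length(extra)) {
      stop("Tukey genes absent from the DEG table in region ", r, ": ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
    pn <- paste0(tk$stage_a, "-", tk$stage_b)
    sig <- tk$p_adj < alpha & tk$gene %in% deg_genes
    counts <- tapply(sig, pn, sum)
    if (is.null(pair_names)) pair_names <<- unique(pn)
    as.numeric(counts[pair_names])
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(pair_names, regions)
  out[is.na(out)] <- 0
  out
}

#' Call adjacent-stage developmental DEGs
#'
#' A developmental DEG at transition (s, s+1) of a region is a temporal DEG
#' whose Tukey mean difference between the two adjacent stages has absolute
#' value at least `min_abs_diff` (log2 scale; inclusive threshold). Requiring
#' additional Tukey significance is optional via
#' `require_tukey_significance`.
#'
#' @param tukey_by_region Named list (by region) of [tukey_hsd()] results.
#' @param degs A `temporal_deg_table` covering the same regions.
#' @param min_abs_diff Minimum absolute adjacent-stage mean difference (> 0).
#' @param require_tukey_significance Also require Tukey `p_adj < alpha`.
#' @param alpha Tukey significance threshold when required.
#' @param stage_order Ordered stage vector defining adjacency; defaults to the
#'   sorted stages present in the first region's Tukey result.
#' @return A `devdeg_set`: named list region -> transition (`"s-t"`) ->
#'   character vector of gene identifiers, with attribute `transitions`.
#' @export
call_developmental_degs <- function(tukey_by_region, degs, min_abs_diff = 1,
                                    require_tukey_significance = FALSE,
                                    alpha = 0.05, stage_order = NULL) {
  if (!is.numeric(min_abs_diff) || min_abs_diff <= 0) {
    stop("min_abs_diff must be > 0")
  }
  regions <- names(tukey_by_region)
  if (is.null(stage_order)) {
    tk1 <- tukey_by_region[[1]]
    stage_order <- sort(unique(c(tk1$stage_a, tk1$stage_b)))
  }
  transitions <- stage_transitions(stage_order)
  out <- lapply(regions, function(r) {
    tk <- tukey_by_region[[r]]
    deg_genes <- degs$gene[degs$region == r & degs$is_temporal_deg]
    sets <- lapply(seq_along(transitions), function(i) {
      a <- stage_order[i]; b <- stage_order[i + 1]
      rows <- tk$stage_a == a & tk$stage_b == b
      keep <- rows & abs(tk$diff) >= min_abs_diff & tk$gene %in% deg_genes
      if (require_tukey_significance) {
        if (anyNA(tk$p_adj[rows])) {
          stop("Tukey p-values missing for region ", r,
               " but require_tukey_significance = TRUE")
        }
        keep <- keep & !is.na(tk$p_adj) & tk$p_adj < alpha
      }
      sort(tk$gene[keep])
    })
    names(sets) <- transitions
    sets
  })
  names(out) <- regions
  structure(out, transitions = transitions, class = "devdeg_set")
}

#' Write developmental DEG sets as JSON
#'
#' @param devdegs A `devdeg_set` from [call_developmental_degs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_devdeg_json <- function(devdegs, path) {
  jsonlite::write_json(unclass(devdegs), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
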