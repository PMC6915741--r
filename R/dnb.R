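#' Stage-wise candidate genes for dynamic network biomarker analysis
#'
#' For every stage after the first, performs a two-sided Welch t-test per
#' gene against the first stage (samples pooled across regions), adjusts
#' p-values across genes with Benjamini-Hochberg, and keeps genes with
#' q below `alpha`.
#'
#' @param data An [expression_dataset()].
#' @param alpha FDR threshold for candidate selection.
#' @param first_stage Reference stage; defaults to the first member of the
#'   declared stage order present in the data.
#' @return Named list, one element per later stage (as character), each a
#'   character vector of candidate genes. Attribute `tables` carries the full
#'   per-stage data frames (`gene`, `t`, `p`, `q`).
#' @export
stagewise_candidates <- function(data, alpha = 0.05, first_stage = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  stages <- data$stage_order[data$stage_order %in% data$meta$stage]
  if (is.null(first_stage)) first_stage <- stages[1]
  if (!first_stage %in% stages) stop("first stage absent: ", first_stage)
  ref_idx <- data$meta$stage == first_stage
  if (sum(ref_idx) < 2) stop("stage ", first_stage, " has fewer than 2 samples")
  X0 <- data$expr[, ref_idx, drop = FALSE]
  n0 <- ncol(X0)
  m0 <- rowMeans(X0)
  v0 <- rowSums((X0 - m0)^2) / (n0 - 1)
  later <- stages[stages != first_stage & match(stages, stages) > match(first_stage, stages)]
  out <- list()
  tables <- list()
  for (s in later) {
    idx <- data$meta$stage == s
    if (sum(idx) < 2) stop("stage ", s, " has fewer than 2 samples")
    X1 <- data$expr[, idx, drop = FALSE]
    n1 <- ncol(X1)
    m1 <- rowMeans(X1)
    v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
    se2 <- v1 / n1 + v0 / n0
    tstat <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    # genes constant in both groups with equal means: no evidence
    degen <- se2 <= .Machine$double.eps
    p[degen] <- ifelse(abs(m1 - m0)[degen] > 0, 0, 1)
    q <- bh_adjust(p)
    tab <- data.frame(gene = rownames(data$expr), t = unname(tstat),
                      p = unname(p), q = unname(q), stringsAsFactors = FALSE)
    out[[as.character(s)]] <- tab$gene[tab$q < alpha]
    tables[[as.character(s)]] <- tab
  }
  attr(out, "tables") <- tables
  attr(out, "first_stage") <- first_stage
  out
}

# stage submatrix with optional removal of per-region means: when samples
# are pooled across regions, regional expression differences would otherwise
# masquerade as within-stage correlation and variance
stage_matrix <- function(data, stage, genes, center_regions = TRUE) {
  idx <- which(data$meta$stage == stage)
  X <- data$expr[genes, idx, drop = FALSE]
  if (center_regions) {
    for (r in unique(data$meta$region[idx])) {
      cols <- data$meta$region[idx] == r
      X[, cols] <- X[, cols, drop = FALSE] -
        rowMeans(X[, cols, drop = FALSE])
    }
  }
  X
}

#' Cluster a stage's candidate genes by expression correlation
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - Pearson correlation` over the stage's samples, cut into
#' `min(max_clusters, n_candidates)` clusters. Genes with zero variance at
#' the stage are treated as uncorrelated with everything (correlation 0).
#' With samples pooled from several regions, per-region means are removed
#' first (see `center_regions`) so the correlations reflect within-stage
#' co-fluctuation rather than regional expression differences.
#'
#' @param data An [expression_dataset()].
#' @param stage Stage whose samples are used (pooled across regions; >= 3
#'   samples required).
#' @param candidates Character vector of genes to cluster (>= 1).
#' @param max_clusters Maximum number of clusters.
#' @param center_regions Remove per-region means within the stage before
#'   computing correlations.
#' @return Integer cluster labels named by gene.
#' @export
cluster_stage_genes <- function(data, stage, candidates, max_clusters = 40,
                                center_regions = TRUE) {
  stopifnot(inherits(data, "expression_dataset"), length(candidates) >= 1)
  idx <- data$meta$stage == stage
  if (sum(idx) < 3) stop("stage ", stage, " has fewer than 3 samples")
  if (length(candidates) == 1L) {
    return(stats::setNames(1L, candidates))
  }
  X <- stage_matrix(data, stage, candidates, center_regions)
  cc <- suppressWarnings(stats::cor(t(X)))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  d <- stats::as.dist(1 - cc)
  tree <- stats::hclust(d, method = "average")
  k <- min(max_clusters, length(candidates))
  stats::setNames(stats::cutree(tree, k = k), candidates)
}

#' Dynamic-network-biomarker statistics of one cluster at one stage
#'
#' Computes, over the stage's samples: the average member standard deviation
#' (`sd_avg`), the average absolute Pearson correlation among member pairs
#' (`pcc_in`; 1 by convention, flagged, for singleton clusters), the average
#' absolute correlation between members and the complement genes
#' (`pcc_out`, floored at 1e-6, flagged when the floor binds), and the
#' composite index `CI = sd_avg * pcc_in / pcc_out`. A rising CI signals a
#' cluster approaching a critical transition: fluctuation and internal
#' coupling grow while coupling to the rest of the network drops. With
#' samples pooled from several regions, per-region means are removed first
#' so regional expression differences do not inflate SD and correlation.
#'
#' @param data An [expression_dataset()].
#' @param stage Stage whose samples are used (>= 3).
#' @param members Character vector of in-cluster genes.
#' @param complement Character vector of out-cluster genes (non-empty).
#' @param center_regions Remove per-region means within the stage first.
#' @return List: `sd_avg`, `pcc_in`, `pcc_out`, `ci`, `flags` (character).
#' @export
cluster_statistics <- function(data, stage, members, complement,
                               center_regions = TRUE) {
  stopifnot(inherits(data, "expression_dataset"), length(members) >= 1)
  if (!length(complement)) stop("empty complement: cluster must not cover all genes")
  if (length(intersect(members, complement))) {
    stop("members and complement overlap")
  }
  idx <- data$meta$stage == stage
  if (sum(idx) < 3) stop("stage ", stage, " has fewer than 3 samples")
  Xm <- stage_matrix(data, stage, members, center_regions)
  Xc <- stage_matrix(data, stage, complement, center_regions)
  flags <- character(0)
  sd_avg <- mean(apply(Xm, 1, stats::sd))
  if (length(members) >= 2) {
    cin <- suppressWarnings(stats::cor(t(Xm)))
    cin[is.na(cin)] <- 0
    pcc_in <- mean(abs(cin[upper.tri(cin)]))
  } else {
    pcc_in <- 1
    flags <- c(flags, "singleton_pcc_in")
  }
  cout <- suppressWarnings(stats::cor(t(Xm), t(Xc)))
  cout[is.na(cout)] <- 0
  pcc_out <- mean(abs(cout))
  if (pcc_out < 1e-6) {
    pcc_out <- 1e-6
    flags <- c(flags, "pcc_out_floored")
  }
  list(sd_avg = sd_avg, pcc_in = pcc_in, pcc_out = pcc_out,
       ci = sd_avg * pcc_in / pcc_out, flags = flags)
}

#' Stage-by-stage dynamic network biomarker trace
#'
#' Screens candidates at every stage against the first stage
#' ([stagewise_candidates()]), clusters each stage's candidates by Pearson
#' correlation with at most `max_clusters` clusters
#' ([cluster_stage_genes()]), and computes the DNB statistics of every
#' cluster with the rest of the expression matrix as the out-cluster
#' complement ([cluster_statistics()]). Stages with fewer than
#' `min_candidates` candidates are skipped.
#'
#' @param data An [expression_dataset()].
#' @param alpha FDR threshold for the stage-wise candidate screen.
#' @param max_clusters Maximum number of clusters per stage.
#' @param use_all_genes If `TRUE`, cluster all genes at every stage instead
#'   of the stage's candidates.
#' @param min_candidates Minimum candidate count for a stage to be evaluated.
#' @param center_regions Remove per-region means within each stage before
#'   computing correlations and SDs.
#' @return A `dnb_trace`: list with `stages` (evaluated stages),
#'   `members` (per stage, list of cluster gene vectors), and `stats`
#'   (data frame: `stage`, `cluster`, `size`, `sd_avg`, `pcc_in`, `pcc_out`,
#'   `ci`, `flags`).
#' @export
dnb_trace <- function(data, alpha = 0.05, max_clusters = 40,
                      use_all_genes = FALSE, min_candidates = 2,
                      center_regions = TRUE) {
  stopifnot(inherits(data, "expression_dataset"))
  cand <- stagewise_candidates(data, alpha = alpha)
  all_genes <- rownames(data$expr)
  stages_out <- integer(0)
  members_out <- list()
  stat_rows <- list()
  for (s_chr in names(cand)) {
    genes <- if (use_all_genes) all_genes else cand[[s_chr]]
    if (length(genes) < min_candidates) next
    s <- as.integer(s_chr)
    labels <- cluster_stage_genes(data, s, genes, max_clusters = max_clusters,
                                  center_regions = center_regions)
    stages_out <- c(stages_out, s)
    clusters <- split(names(labels), labels)
    members_out[[s_chr]] <- clusters
    for (cl in names(clusters)) {
      mem <- clusters[[cl]]
      comp <- setdiff(all_genes, mem)
      st <- cluster_statistics(data, s, mem, comp,
                               center_regions = center_regions)
      stat_rows[[length(stat_rows) + 1L]] <- data.frame(
        stage = s, cluster = as.integer(cl), size = length(mem),
        sd_avg = st$sd_avg, pcc_in = st$pcc_in, pcc_out = st$pcc_out,
        ci = st$ci, flags = paste(st$flags, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  stats_df <- if (length(stat_rows)) do.call(rbind, stat_rows) else
    data.frame(stage = integer(0), cluster = integer(0), size = integer(0),
               sd_avg = numeric(0), pcc_in = numeric(0), pcc_out = numeric(0),
               ci = numeric(0), flags = character(0))
  structure(list(stages = stages_out, members = members_out, stats = stats_df,
                 params = list(alpha = alpha, max_clusters = max_clusters,
                               use_all_genes = use_all_genes)),
            class = "dnb_trace")
}

#' @export
print.dnb_trace <- function(x, ...) {
  cat("dnb_trace over", length(x$stages), "stage(s):",
      paste(x$stages, collapse = " "), "\n")
  if (nrow(x$stats)) {
    top <- x$stats[order(-x$stats$ci), ][1, ]
    cat(sprintf("  max CI %.3f at stage %d (cluster %d, %d genes)\n",
                top$ci, top$stage, top$cluster, top$size))
  }
  invisible(x)
}

#' Select the dynamic network biomarker cluster and tipping stage
#'
#' Matches clusters across consecutive evaluated stages by maximal Jaccard
#' membership overlap, computes the CI change of each matched pair, and
#' returns the cluster and stage with the greatest CI increase (ties broken
#' by the larger CI). When no cluster persists across any stage pair, falls
#' back to the cluster with the global CI maximum, flagged. Clusters smaller
#' than `min_size` are not eligible for selection: with few samples per
#' stage their CI is dominated by correlation sampling noise and by the
#' singleton `pcc_in = 1` convention rather than by coordinated fluctuation.
#'
#' @param trace A `dnb_trace` (>= 2 evaluated stages).
#' @param min_size Minimum member count a cluster needs to be selectable.
#' @return List: `stage`, `cluster`, `genes`, `delta_ci`, `ci`,
#'   `ci_trajectory` (per evaluated stage, the CI of the cluster best
#'   matching the selected one), `fallback` (logical).
#' @export
select_dnb <- function(trace, min_size = 5) {
  stopifnot(inherits(trace, "dnb_trace"))
  if (length(trace$stages) < 2) stop("need at least 2 evaluated stages")
  st <- trace$stats
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  best <- NULL
  for (i in seq_len(length(trace$stages) - 1L)) {
    s_prev <- as.character(trace$stages[i])
    s_next <- as.character(trace$stages[i + 1L])
    prev_cl <- trace$members[[s_prev]]
    next_cl <- trace$members[[s_next]]
    for (cl in names(next_cl)) {
      if (length(next_cl[[cl]]) < min_size) next
      ov <- vapply(prev_cl, jaccard, 0, b = next_cl[[cl]])
      if (!length(ov) || max(ov) == 0) next
      match_cl <- names(prev_cl)[which.max(ov)]
      ci_next <- st$ci[st$stage == as.integer(s_next) & st$cluster == as.integer(cl)]
      ci_prev <- st$ci[st$stage == as.integer(s_prev) & st$cluster == as.integer(match_cl)]
      delta <- ci_next - ci_prev
      cand <- list(stage = as.integer(s_next), cluster = as.integer(cl),
                   delta_ci = delta, ci = ci_next)
      if (is.null(best) || delta > best$delta_ci ||
          (delta == best$delta_ci && ci_next > best$ci)) {
        best <- cand
      }
    }
  }
  fallback <- is.null(best)
  if (fallback) {
    eligible <- st[st$size >= min_size, ]
    if (!nrow(eligible)) eligible <- st
    top <- eligible[order(-eligible$ci), ][1, ]
    best <- list(stage = top$stage, cluster = top$cluster,
                 delta_ci = NA_real_, ci = top$ci)
  }
  sel_genes <- trace$members[[as.character(best$stage)]][[as.character(best$cluster)]]
  traj <- vapply(trace$stages, function(s) {
    cls <- trace$members[[as.character(s)]]
    ov <- vapply(cls, jaccard, 0, b = sel_genes)
    if (!length(ov) || max(ov) == 0) return(NA_real_)
    cl <- names(cls)[which.max(ov)]
    st$ci[st$stage == s & st$cluster == as.integer(cl)]
  }, numeric(1))
  list(stage = best$stage, cluster = best$cluster, genes = sel_genes,
       delta_ci = best$delta_ci, ci = best$ci,
       ci_trajectory = stats::setNames(traj, trace$stages),
       fallback = fallback)
}
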