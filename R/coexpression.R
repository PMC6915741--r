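#' Signed weighted adjacency from a correlation network
#'
#' Computes the signed soft-thresholded adjacency
#' `a_ij = ((1 + cor_ij) / 2)^power` with Pearson correlation, so perfectly
#' anti-correlated genes get adjacency 0 and uncorrelated genes
#' `0.5^power` (about 3.8e-6 at the default power 18). The diagonal is 1.
#'
#' @param expr Numeric matrix, genes x samples, with at least 3 samples.
#' @param power Soft-thresholding exponent (>= 1).
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
signed_adjacency <- function(expr, power = 18) {
  stopifnot(is.matrix(expr), power >= 1)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "))
  }
  a <- ((1 + stats::cor(t(expr))) / 2)^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit index
#'
#' Bins whole-network connectivities `k_i = sum_{j != i} a_ij` into
#' `n_bins` equal-width bins and reports the R-squared of the linear fit of
#' `log10(frequency)` on `log10(mean k)` per occupied bin, sign-adjusted to
#' be negative when the slope is positive (so only decaying degree
#' distributions score highly).
#'
#' @param adjacency Symmetric adjacency matrix (>= 3 genes).
#' @param n_bins Number of connectivity bins.
#' @return Signed R-squared; `NaN` (with attribute `flag`) when all
#'   connectivities are identical.
#' @export
scale_free_fit <- function(adjacency, n_bins = 10) {
  stopifnot(is.matrix(adjacency))
  if (nrow(adjacency) < 3) stop("need at least 3 genes")
  k <- rowSums(adjacency) - diag(adjacency)
  scale_free_fit_k(k, n_bins = n_bins)
}

#' Scale-free fit index from a connectivity vector
#'
#' Workhorse behind [scale_free_fit()], exposed so degree distributions can
#' be assessed directly.
#'
#' @param k Numeric vector of connectivities.
#' @param n_bins Number of equal-width bins.
#' @return Signed R-squared as in [scale_free_fit()].
#' @export
scale_free_fit_k <- function(k, n_bins = 10) {
  if (max(k) - min(k) <= .Machine$double.eps * max(abs(k), 1)) {
    return(structure(NaN, flag = "degenerate: all connectivities identical"))
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0 & mean_k > 0
  x <- log10(mean_k[ok])
  y <- log10(freq[ok] / length(k))
  if (length(x) < 3) return(structure(NaN, flag = "too few occupied bins"))
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  slope <- stats::coef(fit)[2]
  if (is.na(slope)) return(structure(NaN, flag = "degenerate fit"))
  if (slope > 0) -r2 else r2
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with connectivity `k` excluding the diagonal and the sum over
#' `u` excluding `i` and `j`; `TOM_ii = 1`. Genes with high topological
#' overlap share the same network neighbourhood even if their direct
#' adjacency is modest.
#'
#' @param adjacency Symmetric adjacency matrix with entries in `[0, 1]` and
#'   unit diagonal.
#' @return Symmetric TOM matrix with entries in `[0, 1]`.
#' @export
topological_overlap <- function(adjacency) {
  stopifnot(is.matrix(adjacency))
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    stop("adjacency must be symmetric")
  }
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  shared <- a %*% a  # (shared)_ij = sum_{u != i,j} a_iu a_uj for i != j
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules by hybrid dynamic tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut by a hybrid two-step procedure. First, a static cut removes all
#' merges at or above `cut_factor` times the mean off-diagonal dissimilarity
#' (joins at background dissimilarity are noise). Second, each remaining
#' branch is split recursively wherever the merge creating it sits clearly
#' above its children's internal merges — a relative height gap of at least
#' `0.5, 0.4, 0.3, 0.2, 0.1` of the merge height for `deep_split = 0..4`,
#' so larger `deep_split` splits more aggressively. Clusters smaller than
#' `min_module_size`, and clusters whose mean within-cluster TOM does not
#' exceed `cohesion_factor` times the background mean TOM, dissolve to label
#' 0. Finally, unassigned genes whose mean TOM to some module passes the
#' same cohesion bar are adopted by their nearest module. The procedure is
#' deterministic given its input.
#'
#' @param tom TOM (or other similarity) matrix from [topological_overlap()].
#' @param min_module_size Minimum module size (smaller clusters dissolve to
#'   label 0).
#' @param deep_split Integer 0-4; larger values split branches more
#'   aggressively.
#' @param cohesion_factor Multiplier on the background mean TOM a cluster
#'   must exceed to count as a module.
#' @param cut_factor Static cut height as a fraction of the mean off-diagonal
#'   dissimilarity.
#' @return Integer vector of module labels (0 = unassigned), named by gene,
#'   with modules numbered 1, 2, ... in decreasing size order.
#' @export
detect_modules <- function(tom, min_module_size = 50, deep_split = 4,
                           cohesion_factor = 2, cut_factor = 0.98) {
  stopifnot(is.matrix(tom), deep_split %in% 0:4)
  n <- nrow(tom)
  genes <- rownames(tom)
  if (is.null(genes)) genes <- as.character(seq_len(n))
  if (n < min_module_size) {
    warning("fewer genes (", n, ") than min_module_size (", min_module_size,
            "); all genes unassigned")
    return(stats::setNames(integer(n), genes))
  }
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  background <- mean(tom[upper.tri(tom)])
  bar <- cohesion_factor * background
  cut_height <- cut_factor * (1 - background)
  gap_rel <- c(0.5, 0.4, 0.3, 0.2, 0.1)[deep_split + 1]

  # node i of tree$merge has height tree$height[i]; children < 0 are leaves
  node_height <- function(ch) if (ch < 0) 0 else tree$height[ch]
  members_of <- function(node) {
    # iterative subtree leaf collection
    stack <- node
    leaves <- integer(0)
    while (length(stack)) {
      nd <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (nd < 0) leaves <- c(leaves, -nd)
      else stack <- c(stack, tree$merge[nd, ])
    }
    leaves
  }
  # recursive hybrid cut from the root, explicit stack
  cluster_roots <- list()
  stack <- list(n - 1L)  # root internal node
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (nd < 0) {
      cluster_roots[[length(cluster_roots) + 1L]] <- nd  # singleton
      next
    }
    h <- tree$height[nd]
    ch <- tree$merge[nd, ]
    child_top <- max(node_height(ch[1]), node_height(ch[2]))
    split_here <- h >= cut_height ||
      (h > 0 && (h - child_top) / h >= gap_rel)
    if (split_here) {
      stack <- c(stack, ch[1], ch[2])
    } else {
      cluster_roots[[length(cluster_roots) + 1L]] <- nd
    }
  }
  out <- integer(n)
  next_label <- 1L
  for (root in cluster_roots) {
    idx <- if (root < 0) -root else members_of(root)
    if (length(idx) < min_module_size) next
    sub <- tom[idx, idx]
    if (mean(sub[upper.tri(sub)]) <= bar) next
    out[idx] <- next_label
    next_label <- next_label + 1L
  }
  cohesive <- sort(unique(out[out > 0]))

  # adopt unassigned genes whose neighbourhood clearly belongs to one module
  if (length(cohesive)) {
    un <- which(out == 0L)
    if (length(un)) {
      mean_tom <- vapply(cohesive, function(cl) {
        rowMeans(tom[un, out == cl, drop = FALSE])
      }, numeric(length(un)))
      mean_tom <- matrix(mean_tom, nrow = length(un))
      bestmod <- max.col(mean_tom, ties.method = "first")
      bestval <- mean_tom[cbind(seq_along(un), bestmod)]
      adopt <- bestval > bar
      out[un[adopt]] <- cohesive[bestmod[adopt]]
    }
  }
  # renumber by decreasing size
  kept <- sort(table(out[out > 0]), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(kept), names(kept))
  out[out > 0] <- relabel[as.character(out[out > 0])]
  stats::setNames(as.integer(out), genes)
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix, one score
#' per sample, sign-oriented to correlate positively with the module's mean
#' expression profile. A single-gene module returns the standardized gene.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param module_genes Character vector of member genes (non-empty).
#' @return Numeric vector of per-sample eigengene scores (unit variance).
#' @export
module_eigengene <- function(expr, module_genes) {
  stopifnot(length(module_genes) >= 1)
  miss <- setdiff(module_genes, rownames(expr))
  if (length(miss)) stop("unknown gene(s): ", paste(utils::head(miss, 3), collapse = ", "))
  sub <- expr[module_genes, , drop = FALSE]
  z <- t(scale(t(sub)))  # standardize genes
  if (length(module_genes) == 1L) {
    return(stats::setNames(as.numeric(z), colnames(expr)))
  }
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  eg <- pc$x[, 1]
  avg <- colMeans(z)
  if (stats::sd(eg) > 0) eg <- eg / stats::sd(eg)
  ori <- stats::cor(eg, avg)
  if (!is.na(ori) && ori < 0) eg <- -eg
  stats::setNames(eg, colnames(expr))
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the pair of modules whose eigengene dissimilarity
#' `1 - cor` is smallest, as long as it is below `merge_height`, recomputing
#' eigengenes after every merge. Running the procedure twice is a no-op.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Integer module labels (0 = unassigned), named by gene.
#' @param merge_height Dissimilarity cutoff in `[0, 1]` below which modules
#'   merge.
#' @return Updated label vector (renumbered 1, 2, ... by decreasing size).
#' @export
merge_close_modules <- function(expr, labels, merge_height = 0.15) {
  stopifnot(merge_height >= 0, merge_height <= 1)
  labels <- labels[rownames(expr)]
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    egs <- vapply(mods, function(m) {
      module_eigengene(expr, names(labels)[labels == m])
    }, numeric(ncol(expr)))
    cc <- stats::cor(egs)
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (1 - max(cc) >= merge_height) break
    from <- mods[max(best)]
    to <- mods[min(best)]
    labels[labels == from] <- to
  }
  kept <- sort(table(labels[labels > 0]), decreasing = TRUE)
  if (length(kept)) {
    relabel <- stats::setNames(seq_along(kept), names(kept))
    labels[labels > 0] <- relabel[as.character(labels[labels > 0])]
  }
  stats::setNames(as.integer(labels), names(labels))
}

#' Intramodular connectivity
#'
#' Sum of adjacency from each gene to the other genes of its module;
#' unassigned genes (label 0) use whole-network connectivity.
#'
#' @param adjacency Adjacency matrix.
#' @param labels Module labels named by gene (aligned with `adjacency`).
#' @return Numeric vector of connectivities, named by gene.
#' @export
intramodular_connectivity <- function(adjacency, labels) {
  genes <- rownames(adjacency)
  labels <- labels[genes]
  k <- numeric(length(genes))
  for (m in unique(labels)) {
    idx <- which(labels == m)
    if (m == 0) {
      k[idx] <- rowSums(adjacency[idx, , drop = FALSE]) - diag(adjacency)[idx]
    } else {
      k[idx] <- rowSums(adjacency[idx, idx, drop = FALSE]) -
        diag(adjacency)[idx]
    }
  }
  stats::setNames(k, genes)
}

#' Top linked genes of a network
#'
#' Ranks genes by intramodular connectivity (whole-network connectivity for
#' unassigned genes) and returns the top `n`, ties broken by gene identifier.
#'
#' @param adjacency Adjacency matrix.
#' @param labels Module labels named by gene.
#' @param n Number of genes to return (<= gene count).
#' @return Character vector of the `n` most connected genes, in rank order.
#' @export
top_linked_genes <- function(adjacency, labels, n = 300) {
  if (n > nrow(adjacency)) stop("n exceeds the number of genes")
  k <- intramodular_connectivity(adjacency, labels)
  ord <- order(-k, names(k))
  names(k)[ord][seq_len(n)]
}

#' Module enrichment in developmental DEGs
#'
#' Fisher/BH enrichment of every detected module (label > 0) against a
#' developmental DEG gene list; the unassigned label-0 group is not tested.
#'
#' @param labels Module labels named by gene.
#' @param deg_genes Character vector of DEG identifiers.
#' @param universe Character vector of all genes under analysis.
#' @return Data frame: `module`, `size`, `overlap`, `odds_ratio`, `p`, `q`.
#' @export
module_deg_enrichment <- function(labels, deg_genes, universe) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) {
    return(data.frame(module = integer(0), size = integer(0),
                      overlap = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  }
  deg_genes <- intersect(deg_genes, universe)
  rows <- lapply(mods, function(m) {
    members <- intersect(names(labels)[labels == m], universe)
    fe <- fisher_enrichment(members, deg_genes, universe)
    data.frame(module = m, size = length(members),
               overlap = fe$table[1, 1], odds_ratio = fe$odds_ratio,
               p = fe$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Build a signed co-expression network with modules
#'
#' End-to-end convenience wrapper: signed adjacency, TOM, dynamic tree cut,
#' eigengene merging, eigengenes and intramodular connectivity.
#'
#' @param expr Numeric matrix, genes x samples (zero-variance genes are
#'   removed with a message).
#' @param power Soft-thresholding power.
#' @param min_module_size,deep_split,merge_height Module detection and
#'   merging parameters (see [detect_modules()] and [merge_close_modules()]).
#' @return A `coexpression_network` list: `genes`, `adjacency`, `tom`,
#'   `labels`, `eigengenes` (matrix module x sample), `connectivity`,
#'   `scale_free_r2`, `params`.
#' @export
build_coexpression_network <- function(expr, power = 18, min_module_size = 50,
                                       deep_split = 4, merge_height = 0.15) {
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    message("removing ", sum(sds == 0), " zero-variance gene(s)")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  adj <- signed_adjacency(expr, power = power)
  tom <- topological_overlap(adj)
  labels <- detect_modules(tom, min_module_size = min_module_size,
                           deep_split = deep_split)
  labels <- merge_close_modules(expr, labels, merge_height = merge_height)
  mods <- sort(unique(labels[labels > 0]))
  egs <- if (length(mods)) {
    t(vapply(mods, function(m) module_eigengene(expr, names(labels)[labels == m]),
             numeric(ncol(expr))))
  } else {
    matrix(numeric(0), 0, ncol(expr))
  }
  if (length(mods)) rownames(egs) <- paste0("ME", mods)
  structure(
    list(genes = rownames(expr), adjacency = adj, tom = tom, labels = labels,
         eigengenes = egs, connectivity = intramodular_connectivity(adj, labels),
         scale_free_r2 = scale_free_fit(adj),
         params = list(power = power, min_module_size = min_module_size,
                       deep_split = deep_split, merge_height = merge_height)),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  n_mod <- length(unique(x$labels[x$labels > 0]))
  cat("coexpression_network:", length(x$genes), "genes,", n_mod, "modules",
      sprintf("(%d unassigned); power %d, scale-free R2 %.2f\n",
              sum(x$labels == 0), x$params$power, x$scale_free_r2))
  invisible(x)
}
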