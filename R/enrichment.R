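#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line — name, description, then
#' gene identifiers.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: named list of character vectors, each with
#'   a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line (need name, description, >=1 gene): ",
                                substr(ln, 1, 60))
    nm <- parts[1]
    if (nm %in% names(sets)) stop("duplicate gene-set name: ", nm)
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    attr(genes, "description") <- parts[2]
    sets[[nm]] <- genes
  }
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets A named list of character vectors (optionally with
#'   `description` attributes).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(names(sets), function(nm) {
    d <- attr(sets[[nm]], "description")
    if (is.null(d)) d <- ""
    paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability of a 2x2 enrichment table
#'
#' `P(X >= overlap)` with `X ~ Hypergeometric(universe_size, set_size,
#' target_size)`: the one-sided Fisher's exact p-value for
#' over-representation.
#'
#' @param overlap Observed overlap count.
#' @param set_size,universe_size,target_size Table margins.
#' @return Numeric p-value (vectorised over its arguments).
#' @export
hypergeom_tail_p <- function(overlap, set_size, universe_size, target_size) {
  stats::phyper(overlap - 1, set_size, universe_size - set_size, target_size,
                lower.tail = FALSE)
}

#' One-sided Fisher's exact enrichment test
#'
#' Tests over-representation of `target` genes inside `set` against a finite
#' gene universe. The p-value is the exact hypergeometric upper tail
#' `P(X >= overlap)`; the odds ratio is the sample odds ratio, with a 0.5
#' Haldane correction applied (and flagged) only when a table cell is zero.
#'
#' @param set Character vector of genes (e.g. a functional or marker set).
#' @param target Character vector of genes (e.g. a developmental DEG set).
#' @param universe Character vector of all considered genes; `set` and
#'   `target` must be subsets.
#' @return List with `table` (2x2 counts: in/out of `set` by in/out of
#'   `target`), `odds_ratio`, `p`, and `haldane` (logical flag).
#' @export
fisher_enrichment <- function(set, target, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  set <- unique(set)
  target <- unique(target)
  if (length(setdiff(set, universe))) stop("`set` is not a subset of the universe")
  if (length(setdiff(target, universe))) stop("`target` is not a subset of the universe")
  n_u <- length(universe)
  a <- length(intersect(set, target))
  b <- length(set) - a
  c_ <- length(target) - a
  d <- n_u - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                dimnames = list(c("in_set", "out_set"),
                                c("in_target", "out_target")))
  p <- hypergeom_tail_p(a, length(set), n_u, length(target))
  haldane <- any(tab == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  list(table = tab, odds_ratio = or, p = p, haldane = haldane)
}

#' Enrichment of gene sets across regions and transitions
#'
#' Runs [fisher_enrichment()] for every gene set against every region x
#' transition developmental DEG set, then applies Benjamini-Hochberg within
#' each gene set (family = all region x transition cells of that set).
#' Significance stars mark q < 0.05 / 0.01 / 0.001.
#'
#' @param sets A `gene_set_collection` (genes outside `universe` are dropped
#'   with a warning).
#' @param devdegs A `devdeg_set`.
#' @param universe Character vector of expressed genes (the analysis universe).
#' @return An `enrichment_result` data frame: `set`, `region`, `transition`,
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `q`, `stars`.
#' @export
enrichment_matrix <- function(sets, devdegs, universe) {
  stopifnot(inherits(devdegs, "devdeg_set"))
  transitions <- attr(devdegs, "transitions")
  regions <- names(devdegs)
  rows <- list()
  for (nm in names(sets)) {
    s <- intersect(sets[[nm]], universe)
    if (length(s) < length(unique(sets[[nm]]))) {
      warning("gene set ", nm, " trimmed to the universe (",
              length(s), "/", length(unique(sets[[nm]])), " genes kept)")
    }
    for (r in regions) {
      for (tr in transitions) {
        tgt <- intersect(devdegs[[r]][[tr]], universe)
        fe <- fisher_enrichment(s, tgt, universe)
        rows[[length(rows) + 1L]] <- data.frame(
          set = nm, region = r, transition = tr,
          a = fe$table[1, 1], b = fe$table[1, 2],
          c = fe$table[2, 1], d = fe$table[2, 2],
          odds_ratio = fe$odds_ratio, p = fe$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (nm in unique(out$set)) {
    sel <- out$set == nm
    out$q[sel] <- bh_adjust(out$p[sel])
  }
  out$stars <- ifelse(out$q < 0.001, "***",
                      ifelse(out$q < 0.01, "**",
                             ifelse(out$q < 0.05, "*", "")))
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Majority-of-regions cell-type regulation call
#'
#' Summarises per-region enrichment of a marker set at each transition into a
#' single level, using enrichment in a strict majority of regions as the
#' threshold: `High` when the p-value is below 0.001 in more than half of the
#' regions, else `Medium` (p < 0.01 in more than half), else `Low` (p < 0.05
#' in more than half), else `NotEnriched`.
#'
#' @param results An `enrichment_result` from [enrichment_matrix()].
#' @param n_regions Total number of regions the calls are made over.
#' @param p_column Which column carries the p-values to threshold
#'   (`"q"` = BH-adjusted, the default, or `"p"` raw).
#' @return Data frame: `set`, `transition`, `level` (factor with levels
#'   High, Medium, Low, NotEnriched).
#' @export
celltype_call <- function(results, n_regions, p_column = "q") {
  stopifnot(p_column %in% names(results))
  need <- floor(n_regions / 2) + 1  # strict majority
  combos <- unique(results[, c("set", "transition")])
  lvl <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sel <- results$set == combos$set[i] & results$transition == combos$transition[i]
    pv <- results[[p_column]][sel]
    lvl[i] <- if (sum(pv < 0.001) >= need) "High"
    else if (sum(pv < 0.01) >= need) "Medium"
    else if (sum(pv < 0.05) >= need) "Low"
    else "NotEnriched"
  }
  out <- data.frame(set = combos$set, transition = combos$transition,
                    level = factor(lvl, levels = c("High", "Medium", "Low",
                                                   "NotEnriched")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Paired comparison of two marker sets' regional enrichment
#'
#' Compares the enrichment of two marker sets (e.g. excitatory-neuron vs
#' interneuron markers) at one transition with a paired two-sided Wilcoxon
#' signed-rank test across regions, scoring each region by `-log10(p)` of its
#' enrichment.
#'
#' @param results_a,results_b `enrichment_result` rows for the two sets
#'   (each must cover the same regions at `transition`).
#' @param transition Transition label to compare at.
#' @param p_column Column used as the enrichment p-value (default raw `"p"`).
#' @return List with `statistic` (signed-rank V), `p`, and the per-region
#'   score difference vector `differences`.
#' @export
compare_marker_regulation <- function(results_a, results_b, transition,
                                      p_column = "p") {
  ra <- results_a[results_a$transition == transition, ]
  rb <- results_b[results_b$transition == transition, ]
  regions <- intersect(ra$region, rb$region)
  if (length(regions) < 5) stop("fewer than 5 shared regions at transition ",
                                transition)
  sa <- -log10(pmax(ra[[p_column]][match(regions, ra$region)], 1e-300))
  sb <- -log10(pmax(rb[[p_column]][match(regions, rb$region)], 1e-300))
  d <- sa - sb
  if (all(d == 0)) {
    return(list(statistic = 0, p = 1, differences = stats::setNames(d, regions)))
  }
  wt <- suppressWarnings(stats::wilcox.test(sa, sb, paired = TRUE,
                                            alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       differences = stats::setNames(d, regions))
}
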