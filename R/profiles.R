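#' Developmental DEG counts per region and transition
#'
#' @param devdegs A `devdeg_set` from [call_developmental_degs()].
#' @return Integer matrix, regions x transitions, of developmental DEG counts
#'   in declared transition order.
#' @export
profile_counts <- function(devdegs) {
  stopifnot(inherits(devdegs, "devdeg_set"))
  transitions <- attr(devdegs, "transitions")
  out <- t(vapply(devdegs, function(sets) {
    vapply(transitions, function(tr) {
      if (is.null(sets[[tr]])) 0L else length(sets[[tr]])
    }, integer(1))
  }, integer(length(transitions))))
  dimnames(out) <- list(names(devdegs), transitions)
  out
}

#' Detect peak transitions in developmental DEG profiles
#'
#' A transition is a peak when its count exceeds the previous transition's
#' count, is at least the next transition's count (boundary transitions are
#' compared to their single neighbour), and reaches a prominence floor of
#' `min_prominence_fraction` times the profile maximum. Peaks are returned in
#' descending count order. On lifespan neocortex profiles this recovers the
#' twin perinatal and childhood bursts.
#'
#' @param profile Matrix from [profile_counts()] (regions x transitions), or a
#'   single named count vector.
#' @param min_prominence_fraction Prominence floor as a fraction of the
#'   maximum count.
#' @return Named list per region of character vectors of peak transitions
#'   (descending count order); for a vector input, a single character vector.
#' @export
detect_peaks <- function(profile, min_prominence_fraction = 0.2) {
  if (is.matrix(profile)) {
    return(lapply(stats::setNames(rownames(profile), rownames(profile)),
                  function(r) detect_peaks(profile[r, ], min_prominence_fraction)))
  }
  counts <- profile
  n <- length(counts)
  if (n < 3) stop("profile must cover at least 3 transitions")
  if (all(counts == 0)) return(character(0))
  floor_count <- min_prominence_fraction * max(counts)
  is_peak <- logical(n)
  for (t in seq_len(n)) {
    left_ok <- if (t == 1) TRUE else counts[t] > counts[t - 1]
    right_ok <- if (t == n) TRUE else counts[t] >= counts[t + 1]
    if (t == 1) left_ok <- counts[1] >= counts[2]  # single-neighbour rule
    if (t == n) right_ok <- counts[n] > counts[n - 1]
    is_peak[t] <- left_ok && right_ok && counts[t] >= floor_count
  }
  peaks <- which(is_peak)
  peaks <- peaks[order(-counts[peaks], peaks)]
  names(counts)[peaks]
}

#' Proportion of one region's developmental DEGs shared with another
#'
#' Computes `|A intersect B| / |A|` where `A` is `region_a`'s developmental
#' DEG set at the transition. Returns 0 (flagged via attribute
#' `empty_reference`) when `A` is empty.
#'
#' @param devdegs A `devdeg_set`.
#' @param transition Transition label (e.g. `"7-8"`).
#' @param region_a Reference region (denominator).
#' @param region_b Comparison region.
#' @return Numeric scalar in `[0, 1]`.
#' @export
shared_proportion <- function(devdegs, transition, region_a, region_b) {
  stopifnot(inherits(devdegs, "devdeg_set"))
  if (!transition %in% attr(devdegs, "transitions")) {
    stop("unknown transition: ", transition)
  }
  if (!region_a %in% names(devdegs)) stop("unknown region: ", region_a)
  if (!region_b %in% names(devdegs)) stop("unknown region: ", region_b)
  a <- devdegs[[region_a]][[transition]]
  b <- devdegs[[region_b]][[transition]]
  if (!length(a)) {
    return(structure(0, empty_reference = TRUE))
  }
  length(intersect(a, b)) / length(a)
}

#' Permutation test of cross-region developmental DEG overlap
#'
#' The observed statistic is the number of genes present in the developmental
#' DEG sets of at least `min_regions` regions at the transition (default: all
#' regions, i.e. the full intersection). Each permutation redraws, for every
#' region independently, a uniform random gene subset of the same size from
#' the universe and recomputes the statistic. The p-value uses the add-one
#' estimator `(1 + #[null >= observed]) / (1 + n_permutations)`, so it is
#' never exactly zero.
#'
#' @param devdegs A `devdeg_set`.
#' @param transition Transition label.
#' @param universe Character vector of all genes sets are drawn from.
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param min_regions Minimum number of regions a gene must appear in to be
#'   counted as shared; default all regions.
#' @return An `overlap_test` list: `transition`, `observed`, `null_mean`,
#'   `null_sd`, `null` (full vector), `p`, `n_permutations`, `min_regions`,
#'   `seed`.
#' @export
overlap_permutation_test <- function(devdegs, transition, universe,
                                     n_permutations = 10000, seed = 1,
                                     min_regions = NULL) {
  stopifnot(inherits(devdegs, "devdeg_set"), n_permutations >= 1)
  if (!transition %in% attr(devdegs, "transitions")) {
    stop("unknown transition: ", transition)
  }
  sets <- lapply(devdegs, `[[`, transition)
  n_regions <- length(sets)
  if (is.null(min_regions)) min_regions <- n_regions
  stopifnot(min_regions >= 1, min_regions <= n_regions)
  sizes <- lengths(sets)
  if (any(sizes > length(universe))) {
    stop("region set larger than the universe: ",
         paste(names(sets)[sizes > length(universe)], collapse = ", "))
  }
  bad <- vapply(sets, function(s) length(setdiff(s, universe)) > 0, logical(1))
  if (any(bad)) {
    stop("region set(s) not contained in the universe: ",
         paste(names(sets)[bad], collapse = ", "))
  }
  counts <- table(factor(unlist(sets), levels = universe))
  observed <- sum(counts >= min_regions)

  set.seed(seed)
  n_u <- length(universe)
  null <- integer(n_permutations)
  tallies <- integer(n_u)
  for (b in seq_len(n_permutations)) {
    tallies[] <- 0L
    for (sz in sizes) {
      if (sz > 0) {
        idx <- sample.int(n_u, sz)
        tallies[idx] <- tallies[idx] + 1L
      }
    }
    null[b] <- sum(tallies >= min_regions)
  }
  p <- (1 + sum(null >= observed)) / (1 + n_permutations)
  structure(
    list(transition = transition, observed = observed,
         null_mean = mean(null), null_sd = stats::sd(null), null = null,
         p = p, n_permutations = n_permutations,
         min_regions = min_regions, seed = seed),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("overlap_test at transition", x$transition, "\n")
  cat(sprintf("  observed shared genes: %d (>= %d regions)\n",
              x$observed, x$min_regions))
  cat(sprintf("  null: mean %.2f, sd %.2f (%d permutations)\n",
              x$null_mean, x$null_sd, x$n_permutations))
  cat(sprintf("  p = %.4g\n", x$p))
  invisible(x)
}

#' Developmental DEG profile of a dataset
#'
#' One-call wrapper over the adjacent-stage pipeline: temporal DEG calling
#' ([temporal_deg_table()]), adjacent-stage mean differences
#' ([tukey_hsd()], differences only), developmental DEG calling
#' ([call_developmental_degs()]), profile counts and peak detection.
#'
#' @inheritParams subsample_robustness
#' @param min_prominence_fraction Passed to [detect_peaks()].
#' @return List: `degs` (temporal DEG table), `devdegs` (`devdeg_set`),
#'   `profile` (region x transition count matrix), `peaks` (per-region peak
#'   transitions).
#' @export
developmental_profile <- function(data, covariates = character(0),
                                  q_threshold = 0.01, log2_fc_threshold = 1,
                                  min_abs_diff = 1,
                                  min_prominence_fraction = 0.2) {
  stopifnot(inherits(data, "expression_dataset"))
  degs <- temporal_deg_table(data, covariates = covariates,
                             q_threshold = q_threshold,
                             log2_fc_threshold = log2_fc_threshold)
  regions <- sort(unique(data$meta$region))
  tukey <- lapply(stats::setNames(regions, regions), function(r) {
    tukey_hsd(data, r, compute_p = FALSE)
  })
  devdegs <- call_developmental_degs(tukey, degs, min_abs_diff = min_abs_diff,
                                     stage_order = data$stage_order)
  profile <- profile_counts(devdegs)
  list(degs = degs, devdegs = devdegs, profile = profile,
       peaks = detect_peaks(profile, min_prominence_fraction))
}

#' Subsampling robustness of developmental DEG profiles
#'
#' Repeatedly draws `n_per_stage` samples without replacement from every
#' region x stage cell, reruns the full temporal/developmental DEG pipeline on
#' the subsample, and returns the resulting profile. Stability of the peak
#' positions across replicates measures robustness of the profile to sampling
#' depth.
#'
#' @param data An [expression_dataset()].
#' @param n_per_stage Samples to keep per region x stage cell.
#' @param n_reps Number of replicates (0 returns an empty list).
#' @param seed Integer seed.
#' @param covariates,q_threshold,log2_fc_threshold,min_abs_diff Passed to the
#'   DEG pipeline (see [temporal_deg_table()] and [call_developmental_degs()]).
#' @return List of `n_reps` profile matrices (see [profile_counts()]).
#' @export
subsample_robustness <- function(data, n_per_stage, n_reps, seed = 1,
                                 covariates = character(0),
                                 q_threshold = 0.01, log2_fc_threshold = 1,
                                 min_abs_diff = 1) {
  stopifnot(inherits(data, "expression_dataset"), n_per_stage >= 2)
  if (n_reps == 0) return(list())
  cell <- interaction(data$meta$region, data$meta$stage, drop = TRUE)
  sizes <- table(cell)
  if (any(sizes < n_per_stage)) {
    stop("cell(s) with fewer than ", n_per_stage, " samples: ",
         paste(utils::head(names(sizes)[sizes < n_per_stage], 5), collapse = ", "))
  }
  set.seed(seed)
  lapply(seq_len(n_reps), function(b) {
    keep <- unlist(lapply(split(data$meta$sample_id, cell), function(ids) {
      sample(ids, n_per_stage)
    }), use.names = FALSE)
    sub <- subset_samples(data, keep)
    developmental_profile(sub, covariates = covariates,
                          q_threshold = q_threshold,
                          log2_fc_threshold = log2_fc_threshold,
                          min_abs_diff = min_abs_diff)$profile
  })
}
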