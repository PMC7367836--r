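# Permutation (shuffle) enrichment test for CTCF binding at TAD
# boundaries: size-matched random non-overlapping intervals, excluding
# the observed boundary loci, compared on peak-overlap counts.
#
# The null loop runs tens of thousands of shuffles, so the inner
# overlap tests use a findInterval scan over merged sorted intervals
# rather than per-iteration interval-tree construction.

# Precompute a fast overlap index: merged disjoint intervals per chrom.
overlap_index <- function(x) {
  m <- merge_intervals(x)
  split(m[c("start", "end")], m$chrom)
}

# For query vectors (chrom, start, end), TRUE where the query overlaps
# any indexed interval. Intervals 0-based half-open.
overlaps_any <- function(chrom, start, end, index) {
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    iv <- index[[ch]]
    if (is.null(iv) || nrow(iv) == 0) next
    sel <- which(chrom == ch)
    # candidate: last indexed interval starting before the query end
    idx <- findInterval(end[sel] - 1e-9, iv$start)
    hit <- idx >= 1 & iv$end[pmax(idx, 1)] > start[sel]
    out[sel] <- hit
  }
  out
}

#' CTCF enrichment at TAD boundaries by interval shuffling
#'
#' The observed statistic is the number of boundaries overlapping at
#' least one peak. Each null iteration places size-matched random
#' intervals uniformly (by default on the same chromosome as the
#' boundary they match), mutually non-overlapping and excluding the
#' observed boundary loci — the in-process equivalent of
#' `bedtools shuffle -noOverlapping -excl <boundaries>`. The empirical
#' p-value uses the add-one estimator (1 + #null >= observed) /
#' (1 + n_iter), so p is never 0.
#'
#' @param peaks peak tibble (`chrom`, `start`, `end`).
#' @param boundaries boundary tibble (`chrom`, `start`, `end`).
#' @param genome genome table (placement universe).
#' @param n_iter shuffle iterations (default 1000).
#' @param seed RNG seed.
#' @param chrom_constrained keep each shuffled interval on its own
#'   chromosome (default `TRUE`).
#' @param max_retries resampling rounds before giving up on a
#'   non-overlapping placement.
#' @return An object of class `enrichment_result`: `observed`,
#'   `null` (per-iteration counts), `null_mean`, `null_sd`, `fold`
#'   (observed / null mean), `p_value`, `n_iter`, `seed`, `n_intervals`.
#'   [glance()] gives a one-row tibble.
#' @export
ctcf_boundary_enrichment <- function(peaks, boundaries, genome,
                                     n_iter = 1000, seed = 1,
                                     chrom_constrained = TRUE,
                                     max_retries = 1000) {
  assert_columns(boundaries, c("chrom", "start", "end"), "boundaries")
  assert_columns(genome, c("chrom", "length"), "genome")
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  check_intervals_in_genome(boundaries, genome, "boundaries")
  if (nrow(peaks) > 0) check_intervals_in_genome(peaks, genome, "peaks")
  peak_idx <- overlap_index(peaks)
  excl_idx <- overlap_index(boundaries)
  observed <- sum(overlaps_any(boundaries$chrom, boundaries$start,
                               boundaries$end, peak_idx))
  set.seed(seed)
  null <- vapply(seq_len(n_iter), function(i) {
    sh <- shuffle_starts(boundaries$chrom, boundaries$end - boundaries$start,
                         genome, excl_idx = excl_idx,
                         chrom_constrained = chrom_constrained,
                         max_retries = max_retries)
    sum(overlaps_any(sh$chrom, sh$start, sh$end, peak_idx))
  }, numeric(1))
  nm <- mean(null)
  fold <- if (nm == 0) {
    if (observed == 0) 0 else Inf
  } else observed / nm
  structure(list(observed = observed, null = null, null_mean = nm,
                 null_sd = sd(null), fold = fold,
                 p_value = (1 + sum(null >= observed)) / (1 + n_iter),
                 n_iter = n_iter, seed = seed,
                 n_intervals = nrow(boundaries)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Shuffle enrichment: observed %d / %d, null %.2f +/- %.2f, fold %.2f, p = %.4g (%d iterations)\n",
    x$observed, x$n_intervals, x$null_mean, x$null_sd, x$fold, x$p_value,
    x$n_iter))
  invisible(x)
}

# vectorized placement core shared by shuffle_intervals() and the
# enrichment loop; returns a list of chrom/start/end vectors
shuffle_starts <- function(chroms, widths, genome, excl_idx = NULL,
                           chrom_constrained = TRUE, max_retries = 1000) {
  n <- length(chroms)
  glen <- setNames(genome$length, genome$chrom)
  if (!chrom_constrained) {
    chroms <- sample(genome$chrom, n, replace = TRUE,
                     prob = genome$length / sum(genome$length))
  }
  room <- glen[chroms] - widths
  if (any(room < 0)) abort("Interval longer than its chromosome.")
  start <- floor(runif(n) * (room + 1))
  for (try in seq_len(max_retries)) {
    end <- start + widths
    bad <- logical(n)
    if (!is.null(excl_idx)) {
      bad <- overlaps_any(chroms, start, end, excl_idx)
    }
    ord <- order(chroms, start, method = "radix")
    oc <- chroms[ord]; os <- start[ord]; oe <- end[ord]
    if (n > 1) {
      clash <- which(oc[-1] == oc[-n] & os[-1] < cummax_by(oe[-n], oc[-n]))
      bad[ord[clash + 1]] <- TRUE
    }
    if (!any(bad)) {
      return(list(chrom = chroms, start = unname(start), end = unname(end)))
    }
    start[bad] <- floor(runif(sum(bad)) * (room[bad] + 1))
  }
  abort("Could not place non-overlapping shuffled intervals; genome too small.")
}

#' Place size-matched random non-overlapping intervals
#'
#' Uniform placement of intervals size-matched to `intervals`, mutually
#' non-overlapping, avoiding `excl`.
#'
#' @param intervals intervals to size-match (`chrom`, `start`, `end`).
#' @param genome genome table.
#' @param excl intervals the placement must avoid (merged internally).
#' @param chrom_constrained keep each interval on its chromosome.
#' @param max_retries resampling rounds; exceeded -> error (genome too
#'   crowded).
#' @return Tibble `chrom`, `start`, `end` of the shuffled intervals.
#' @export
shuffle_intervals <- function(intervals, genome, excl = NULL,
                              chrom_constrained = TRUE, max_retries = 1000) {
  if (nrow(intervals) == 0) return(intervals[c("chrom", "start", "end")])
  excl_idx <- if (!is.null(excl) && nrow(excl) > 0) overlap_index(excl)
  sh <- shuffle_starts(intervals$chrom, intervals$end - intervals$start,
                       genome, excl_idx = excl_idx,
                       chrom_constrained = chrom_constrained,
                       max_retries = max_retries)
  tibble(chrom = sh$chrom, start = sh$start, end = sh$end)
}

# cummax within runs of equal group labels (labels assumed sorted)
cummax_by <- function(x, g) {
  out <- x
  r <- rle(g)
  pos <- 1
  for (len in r$lengths) {
    idx <- pos:(pos + len - 1)
    out[idx] <- cummax(x[idx])
    pos <- pos + len
  }
  out
}
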