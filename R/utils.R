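# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Gaussian smoothing of a numeric vector with missing-data awareness
#'
#' Convolves `x` with a Gaussian kernel of standard deviation `sigma`
#' (in vector positions), truncated at 4 sigma. `NA` positions neither
#' contribute to nor receive values; each contiguous non-`NA` run is
#' smoothed independently with edge renormalization, so the kernel mass
#' that falls outside the run is redistributed rather than treated as
#' zero signal.
#'
#' @param x numeric vector, possibly with `NA` runs.
#' @param sigma kernel standard deviation in positions; `0` is the identity.
#' @return numeric vector of the same length, `NA` exactly where `x` is `NA`.
#' @examples
#' gauss_smooth(c(0, 0, 1, 0, 0), sigma = 1)
#' @export
gauss_smooth <- function(x, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma < 0) {
    abort("`sigma` must be a single non-negative number.")
  }
  if (sigma == 0 || length(x) == 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  offs <- (-half):half
  kern <- exp(-(offs^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  out <- rep(NA_real_, length(x))
  runs <- na_runs(x)
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    v <- x[idx]
    nv <- length(v)
    num <- rep(0, nv)
    den <- rep(0, nv)
    for (k in seq_along(offs)) {
      o <- offs[k]
      src <- seq_len(nv) + o
      ok <- src >= 1 & src <= nv
      num[ok] <- num[ok] + kern[k] * v[src[ok]]
      den[ok] <- den[ok] + kern[k]
    }
    out[idx] <- num / den
  }
  out
}

# Contiguous non-NA runs as a data frame of (start, end) indices.
na_runs <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(data.frame(start = integer(), end = integer()))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Overlap join of two interval tibbles (0-based half-open) on shared
# chromosomes. Returns a tibble of (idx_x, idx_y) row-index pairs.
# `min_overlap` in bp (1 = any overlap).
overlap_pairs <- function(x, y) {
  assert_columns(x, c("chrom", "start", "end"), "x")
  assert_columns(y, c("chrom", "start", "end"), "y")
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble(idx_x = integer(), idx_y = integer()))
  }
  # half-open [start, end) -> 1-based closed [start + 1, end]
  qr <- IRanges::IRanges(start = x$start + 1, end = x$end)
  sr <- IRanges::IRanges(start = y$start + 1, end = y$end)
  hits <- IRanges::findOverlaps(qr, sr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same <- x$chrom[qi] == y$chrom[si]
  tibble(idx_x = qi[same], idx_y = si[same])
}

# Merge possibly-overlapping intervals within chromosomes; returns sorted
# disjoint intervals.
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(x[c("chrom", "start", "end")])
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  out <- vector("list", length(unique(x$chrom)))
  i <- 0
  for (ch in unique(x$chrom)) {
    xi <- x[x$chrom == ch, ]
    new_grp <- cumsum(c(TRUE, xi$start[-1] > cummax(xi$end[-nrow(xi)])))
    m <- xi %>%
      mutate(grp = new_grp) %>%
      group_by(.data$grp) %>%
      summarise(chrom = ch, start = min(.data$start), end = max(.data$end),
                .groups = "drop") %>%
      select("chrom", "start", "end")
    i <- i + 1
    out[[i]] <- m
  }
  bind_rows(out)
}

round_half_up <- function(x) floor(x + 0.5)
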