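# TAD boundaries from contact matrices via a diamond insulation
# (TAD-separation) score, gene architecture classification, and the
# shuffle-based CTCF enrichment test.

#' Construct a contact matrix object
#'
#' @param mat square, symmetric, non-negative numeric matrix of contact
#'   counts/frequencies for one chromosome.
#' @param chrom chromosome name.
#' @param bin_size matrix bin width in bp.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(mat, chrom, bin_size) {
  if (!is.matrix(mat) || nrow(mat) == 0 || nrow(mat) != ncol(mat)) {
    abort("`mat` must be a non-empty square matrix.")
  }
  if (any(mat < 0, na.rm = TRUE)) abort("Contacts must be non-negative.")
  if (max(abs(mat - t(mat))) > 1e-6 * max(1, max(abs(mat)))) {
    abort("`mat` must be symmetric.")
  }
  structure(list(mat = mat, chrom = chrom, bin_size = bin_size),
            class = "contact_matrix")
}

#' Read a contact matrix from text
#'
#' @param path file path: either a dense whitespace-delimited square
#'   matrix, or a 3-column (bin_i, bin_j, value) TSV with 0-based bin
#'   indices (missing cells are 0, symmetry filled in).
#' @param chrom chromosome name.
#' @param bin_size bin width in bp.
#' @param format `"dense"` or `"triplet"`.
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(path, chrom, bin_size,
                                format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    mat <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(mat) <- NULL
  } else {
    tr <- readr::read_tsv(path, col_names = c("i", "j", "value"),
                          col_types = "iid", progress = FALSE)
    n <- max(tr$i, tr$j) + 1
    mat <- matrix(0, n, n)
    mat[cbind(tr$i + 1, tr$j + 1)] <- tr$value
    mat[cbind(tr$j + 1, tr$i + 1)] <- tr$value
  }
  contact_matrix(mat, chrom, bin_size)
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("Contact matrix: %s, %d bins @ %g bp\n",
              x$chrom, nrow(x$mat), x$bin_size))
  invisible(x)
}

#' TAD-separation (diamond insulation) score
#'
#' For each bin i, the mean contact over the `window_bins` x
#' `window_bins` diamond pairing the window upstream of i with the
#' window downstream, in log2 ratio to the chromosome-wide mean
#' diamond. Strong boundaries are local minima (little contact across
#' them). The score is invariant to global scaling of the matrix. Bins
#' within `window_bins` of either chromosome end are masked.
#'
#' @param cm a `contact_matrix`.
#' @param window_bins diamond half-width in bins (default 10).
#' @param windows optional vector of window sizes; when given, the
#'   score is the mean of single-window scores (multi-window variant).
#' @return Tibble `chrom`, `bin` (0-based), `start`, `end`, `score`
#'   (`NA` where masked).
#' @export
separation_score <- function(cm, window_bins = 10, windows = NULL) {
  if (!inherits(cm, "contact_matrix")) abort("`cm` must be a contact_matrix.")
  ws <- windows %||% window_bins
  n <- nrow(cm$mat)
  if (n < 2 * max(ws) + 1) abort("Matrix too small for the window.")
  score_one <- function(w) {
    # summed-area table for O(1) diamond sums
    sat <- apply(apply(cm$mat, 2, cumsum), 1, cumsum)  # sat[j, i] transposed
    sat <- t(sat)
    rect_sum <- function(r1, r2, c1, c2) {
      sat[cbind(r2, c2)] -
        ifelse(r1 > 1, sat[cbind(pmax(r1 - 1, 1), c2)], 0) -
        ifelse(c1 > 1, sat[cbind(r2, pmax(c1 - 1, 1))], 0) +
        ifelse(r1 > 1 & c1 > 1, sat[cbind(pmax(r1 - 1, 1), pmax(c1 - 1, 1))], 0)
    }
    d <- rep(NA_real_, n)
    i <- (w + 1):(n - w)
    d[i] <- rect_sum(i - w, i - 1, i + 1, i + w) / (w * w)
    log2(d / mean(d, na.rm = TRUE))
  }
  s <- rowMeans(do.call(cbind, lapply(ws, score_one)), na.rm = FALSE)
  bin <- seq_len(n) - 1L
  tibble(chrom = cm$chrom, bin = bin, start = bin * cm$bin_size,
         end = (bin + 1) * cm$bin_size, score = s)
}

#' Call TAD boundaries from a separation-score track
#'
#' Boundaries are local minima of the score with prominence at least
#' `min_depth`, taken greedily from the deepest up, enforcing a minimum
#' separation. A boundary is represented as its single matrix bin.
#'
#' @param score output of [separation_score()].
#' @param min_depth minimum prominence in log2 units (default 0.3).
#' @param min_separation_bins minimum spacing between called boundaries
#'   (default 4).
#' @return Tibble `chrom`, `start`, `end`, `bin`, `score`, sorted by
#'   position; zero rows when nothing qualifies.
#' @export
call_boundaries <- function(score, min_depth = 0.3, min_separation_bins = 4) {
  assert_columns(score, c("chrom", "bin", "start", "end", "score"), "score")
  s <- score$score
  n <- length(s)
  cand <- integer()
  for (i in seq_len(n)) {
    v <- s[i]
    if (is.na(v)) next
    l <- if (i > 1) s[i - 1] else NA
    r <- if (i < n) s[i + 1] else NA
    is_min <- (is.na(l) || v <= l) && (is.na(r) || v <= r) &&
      ((!is.na(l) && v < l) || (!is.na(r) && v < r))
    if (is_min) cand <- c(cand, i)
  }
  if (length(cand) == 0) return(score[0, ])
  prominence <- vapply(cand, function(i) {
    v <- s[i]
    walk <- function(idx) {
      m <- -Inf
      for (j in idx) {
        if (is.na(s[j]) || s[j] < v) break
        m <- max(m, s[j])
      }
      m
    }
    left <- walk(rev(seq_len(i - 1)))
    right <- walk(seq(i + 1, length.out = n - i))
    min(left, right) - v
  }, numeric(1))
  keep <- which(prominence >= min_depth)
  if (length(keep) == 0) return(score[0, ])
  cand <- cand[keep]
  cand <- cand[order(s[cand])]  # deepest first
  accepted <- integer()
  for (i in cand) {
    if (all(abs(i - accepted) >= min_separation_bins)) {
      accepted <- c(accepted, i)
    }
  }
  score[sort(accepted), ] %>% arrange(.data$start)
}

#' Read TAD boundaries from a BED file
#'
#' @param path BED3+ path; a 5th column, when present, is kept as the
#'   separation score.
#' @return Boundary tibble `chrom`, `start`, `end`, `score`.
#' @export
read_boundaries <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  score = numeric()))
  }
  f <- stringr::str_split_fixed(lines, "\t", 6)
  tibble(chrom = f[, 1], start = as.numeric(f[, 2]), end = as.numeric(f[, 3]),
         score = suppressWarnings(as.numeric(f[, 5]))) %>%
    arrange(.data$chrom, .data$start)
}

#' Classify genes as boundary-spanning or intra-TAD
#'
#' A gene spans a boundary iff at least one boundary midpoint lies
#' strictly inside the gene body (a midpoint exactly at the gene start
#' or end does not count).
#'
#' @param genes gene table.
#' @param boundaries boundary tibble (`chrom`, `start`, `end`).
#' @return Tibble `gene_id`, `spans_boundary`, `architecture`
#'   (`"boundary_spanning"` / `"intra_TAD"`), `boundary_ids` (list
#'   column of `chrom:mid` keys).
#' @export
classify_gene_architecture <- function(genes, boundaries) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  mids <- boundaries %>%
    mutate(mid = floor((.data$start + .data$end) / 2)) %>%
    transmute(chrom = .data$chrom, start = .data$mid,
              end = .data$mid + 1,
              bid = paste0(.data$chrom, ":", .data$mid))
  # strict interior: mid in (gene_start, gene_end) <=> the point bin
  # [mid, mid + 1) overlaps [gene_start + 1, gene_end); width-0 intervals
  # (single-bp genes) match nothing
  interior <- genes %>%
    transmute(chrom = .data$chrom, start = .data$start + 1, end = .data$end)
  hits <- overlap_pairs(interior, mids)
  bids <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) bids[[i]] <- character()
  if (nrow(hits) > 0) {
    sp <- split(mids$bid[hits$idx_y], hits$idx_x)
    bids[as.integer(names(sp))] <- sp
  }
  spans <- lengths(bids) > 0
  tibble(gene_id = genes$gene_id, spans_boundary = spans,
         architecture = if_else(spans, "boundary_spanning", "intra_TAD"),
         boundary_ids = bids)
}

#' Flag genes bound by CTCF
#'
#' @param genes gene table.
#' @param peaks peak tibble (`chrom`, `start`, `end`; extra narrowPeak
#'   columns ignored).
#' @return Tibble `gene_id`, `ctcf_bound` (any gene-body overlap).
#' @export
ctcf_gene_binding <- function(genes, peaks) {
  hits <- overlap_pairs(genes, peaks)
  tibble(gene_id = genes$gene_id,
         ctcf_bound = seq_len(nrow(genes)) %in% hits$idx_x)
}
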