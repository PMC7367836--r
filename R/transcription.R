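# Nascent-transcription quantification (Bru-seq style) and gene
# size/expression classification.

#' Quantify nascent transcription per gene
#'
#' Gene-body (intron-inclusive, correct for nascent RNA) read density:
#' reads overlapping the gene body (partial bins prorated by overlapped
#' fraction) scaled by 1e6 / library_size and divided by gene length in
#' kb, i.e. per-kb RPM. When both the count track and the genes carry
#' strand, only matching-strand counts are used.
#'
#' @param counts binned count track at fine resolution (1 kb typical):
#'   tibble `chrom`, `start`, `end`, `value`, optional `strand`.
#' @param library_size total parsed reads in the library.
#' @param genes gene table.
#' @param silence_floor per-kb RPM below which a gene is called silent
#'   (default 0.5).
#' @param condition condition label carried through.
#' @return Tibble `gene_id`, `condition`, `density` (per-kb RPM),
#'   `expressed`.
#' @export
quantify_expression <- function(counts, library_size, genes,
                                silence_floor = 0.5, condition = "control") {
  assert_columns(counts, c("chrom", "start", "end", "value"), "counts")
  assert_columns(genes, c("gene_id", "chrom", "start", "end", "length"),
                 "genes")
  if (library_size <= 0) abort("`library_size` must be > 0.")
  if (any(counts$value < 0, na.rm = TRUE)) abort("Counts must be non-negative.")
  extent <- counts %>% group_by(.data$chrom) %>%
    summarise(max_end = max(.data$end), .groups = "drop")
  chk <- genes %>% left_join(extent, by = "chrom")
  if (any(is.na(chk$max_end) | chk$end > chk$max_end)) {
    bad <- chk$gene_id[is.na(chk$max_end) | chk$end > chk$max_end]
    abort(sprintf("Gene(s) outside the counted genome: %s",
                  paste(bad, collapse = ", ")))
  }
  stranded <- "strand" %in% names(counts) && "strand" %in% names(genes) &&
    any(counts$strand %in% c("+", "-"))
  hits <- overlap_pairs(genes, counts)
  ov_start <- pmax(genes$start[hits$idx_x], counts$start[hits$idx_y])
  ov_end <- pmin(genes$end[hits$idx_x], counts$end[hits$idx_y])
  frac <- (ov_end - ov_start) /
    (counts$end[hits$idx_y] - counts$start[hits$idx_y])
  contrib <- frac * dplyr::coalesce(counts$value[hits$idx_y], 0)
  if (stranded) {
    match_ok <- !(genes$strand[hits$idx_x] %in% c("+", "-")) |
      counts$strand[hits$idx_y] == genes$strand[hits$idx_x]
    contrib[!match_ok] <- 0
  }
  totals <- tibble(idx_x = hits$idx_x, contrib = contrib) %>%
    group_by(.data$idx_x) %>%
    summarise(reads = sum(.data$contrib), .groups = "drop")
  reads <- rep(0, nrow(genes))
  reads[totals$idx_x] <- totals$reads
  density <- (reads * 1e6 / library_size) / (genes$length / 1000)
  tibble(gene_id = genes$gene_id, condition = condition,
         density = density, expressed = density >= silence_floor)
}

#' Assign expression quartiles
#'
#' Quartile cut points come from the density distribution over all
#' supplied genes (optionally only the expressed ones); q1 is the
#' lowest quartile (containing silent genes), q4 the highest. "Highly
#' transcribed" downstream means q3 or q4 — genes above the median.
#'
#' @param records output of [quantify_expression()].
#' @param expressed_only restrict the quartile frame to expressed genes
#'   (unexpressed genes are then all q1). Default `FALSE`.
#' @return `records` plus `quartile` (`"q1"`..`"q4"`) and
#'   `highly_transcribed`.
#' @export
classify_quartiles <- function(records, expressed_only = FALSE) {
  assert_columns(records, c("gene_id", "density"), "records")
  if (nrow(records) < 4) abort("Need >= 4 genes for quartiles.")
  q <- rep(1L, nrow(records))
  scope <- if (expressed_only) which(records$expressed) else
    seq_len(nrow(records))
  if (length(unique(records$density[scope])) <= 1) {
    warn("All densities identical; every gene labeled q1.")
  } else {
    q[scope] <- ntile(records$density[scope], 4)
  }
  records %>%
    mutate(quartile = paste0("q", q),
           highly_transcribed = .data$quartile %in% c("q3", "q4"))
}

#' Classify genes by size
#'
#' Genes longer than `large_cutoff` (300 kb, the classic large-gene
#' fragility threshold) are "large"; genes above `late_cutoff` (250 kb,
#' the size past which genes tend to replicate later) but not large are
#' "medium"; the rest "small". Large genes are split into four length
#' quartile subgroups, L1 = largest.
#'
#' @param genes gene table.
#' @param large_cutoff,late_cutoff bp cutoffs.
#' @return Tibble `gene_id`, `length`, `size_class`, `large_subgroup`
#'   (`NA` for non-large genes), `is_large`.
#' @export
classify_sizes <- function(genes, large_cutoff = 3e5, late_cutoff = 2.5e5) {
  assert_columns(genes, c("gene_id", "length"), "genes")
  if (any(genes$length <= 0)) abort("Gene lengths must be > 0.")
  size_class <- dplyr::case_when(
    genes$length > large_cutoff ~ "large",
    genes$length >= late_cutoff ~ "medium",
    TRUE ~ "small")
  sub <- rep(NA_character_, nrow(genes))
  big <- size_class == "large"
  if (sum(big) >= 1) {
    sub[big] <- paste0("L", ntile(dplyr::desc(genes$length[big]),
                                  min(4L, sum(big))))
  }
  tibble(gene_id = genes$gene_id, length = genes$length,
         size_class = size_class, large_subgroup = sub,
         is_large = big)
}
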