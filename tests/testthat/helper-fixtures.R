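# Shared fixture builders and independent brute-force oracles.
# Oracles are deliberately naive (per-bp loops, all-pairs scans) so they
# share no code path with the implementation they check.

library(dplyr)
library(tibble)

tiny_genome <- function(len = 1e5, n = 1) {
  genome_table(paste0("chr", seq_len(n)), rep(len, n))
}

# long RT-profile tibble from named value vectors; names starting with
# "APH" get condition APH, everything else control
make_profiles <- function(values, bin_size = 5000, chrom = "chr1") {
  n <- length(values[[1]])
  bind_rows(lapply(names(values), function(s) {
    tibble(chrom = chrom,
           start = (seq_len(n) - 1) * bin_size,
           end = seq_len(n) * bin_size,
           sample = s,
           condition = ifelse(grepl("^APH", s), "APH", "control"),
           replicate = as.integer(sub(".*_", "", s)),
           rt = values[[s]])
  }))
}

# per-bp accumulation oracle for length-weighted binning
oracle_bin_bp <- function(intervals, chrom_len, bin_size) {
  val <- rep(NA_real_, chrom_len)
  for (i in seq_len(nrow(intervals))) {
    idx <- (intervals$start[i] + 1):intervals$end[i]
    val[idx] <- intervals$value[i]
  }
  n_bins <- ceiling(chrom_len / bin_size)
  sapply(seq_len(n_bins), function(b) {
    v <- val[((b - 1) * bin_size + 1):min(b * bin_size, chrom_len)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}

# direct O(n^2) renormalized Gaussian convolution (no NA support)
oracle_gauss <- function(x, sigma) {
  n <- length(x)
  half <- max(1L, ceiling(4 * sigma))
  sapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    w <- exp(-((j - i)^2) / (2 * sigma^2))
    sum(w * x[j]) / sum(w)
  })
}

# all-pairs interval overlap oracle (0-based half-open)
oracle_overlaps <- function(a, b) {
  out <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      out[i, j] <- a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]
    }
  }
  out
}

# random non-overlapping intervals on one chromosome
random_intervals <- function(n, chrom_len, max_width, chrom = "chr1") {
  starts <- sort(sample.int(chrom_len - max_width, n))
  widths <- sample.int(max_width, n, replace = TRUE)
  ends <- pmin(starts + widths, c(starts[-1], chrom_len))
  keep <- ends > starts
  tibble(chrom = chrom, start = starts[keep], end = ends[keep])
}

# small planted simulation shared by fragility/pipeline tests
small_sim_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosomes = 2, chrom_length = 2e7,
         n_genes = 100, n_fragile = 4, n_intra_tad_controls = 4,
         n_advanced = 4, n_replicates = 2),
    list(...))
  do.call(simulation_config, args)
}

profiles_from_counts <- function(counts) {
  counts %>%
    dplyr::group_by(.data$sample, .data$condition, .data$replicate) %>%
    dplyr::group_map(function(.x, .y) compute_rt_profile(
      tibble(chrom = .x$chrom, start = .x$start, end = .x$end,
             value = .x$early),
      tibble(chrom = .x$chrom, start = .x$start, end = .x$end,
             value = .x$late),
      sample_id = .y$sample, condition = .y$condition,
      replicate = .y$replicate)) %>%
    bind_rows()
}
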