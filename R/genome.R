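# Genome tables and bin tilings: the coordinate frame every track lives in.
# All coordinates are 0-based half-open (BED convention); 1-based inputs
# (GTF) are converted at the parsing boundary.

#' Build a genome table
#'
#' A genome table is the declared universe of chromosomes and lengths;
#' intervals on chromosomes absent from it are rejected throughout the
#' package.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length positive integer vector of chromosome lengths in bp.
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_table(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_table <- function(chrom, length) {
  if (length(chrom) != length(length)) {
    abort("`chrom` and `length` must have the same length.")
  }
  chrom <- as.character(chrom)
  if (any(is.na(chrom) | chrom == "")) abort("Chromosome names must be non-empty.")
  if (anyDuplicated(chrom)) abort("Chromosome names must be unique.")
  length <- as.numeric(length)
  if (any(is.na(length) | length <= 0)) abort("Chromosome lengths must be > 0.")
  tibble(chrom = chrom, length = length)
}

#' Read a two-column chrom-sizes file into a genome table
#'
#' @param path path to a tab-separated file with columns chromosome, length.
#' @return A genome table tibble (see [genome_table()]).
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "length"),
                        col_types = readr::cols(chrom = "c", length = "d"),
                        progress = FALSE)
  genome_table(df$chrom, df$length)
}

#' Tile a genome into fixed-width bins
#'
#' Produces the canonical bin frame used by all binned tracks: non-
#' overlapping `bin_size` windows per chromosome, the last bin truncated
#' at the chromosome end.
#'
#' @param genome a genome table.
#' @param bin_size bin width in bp.
#' @return A tibble with columns `chrom`, `start`, `end`, `bin`
#'   (0-based bin index within chromosome).
#' @export
tile_genome <- function(genome, bin_size) {
  assert_columns(genome, c("chrom", "length"), "genome")
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size < 1) {
    abort("`bin_size` must be a single positive number.")
  }
  purrr::map2(genome$chrom, genome$length, function(ch, len) {
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    tibble(chrom = ch, start = start,
           end = pmin(start + bin_size, len),
           bin = seq_len(n) - 1L)
  }) %>% bind_rows()
}

check_intervals_in_genome <- function(x, genome, what = "intervals") {
  bad_chrom <- setdiff(unique(x$chrom), genome$chrom)
  if (length(bad_chrom) > 0) {
    abort(sprintf("%s on unknown chromosome(s): %s",
                  what, paste(bad_chrom, collapse = ", ")))
  }
  len <- setNames(genome$length, genome$chrom)
  over <- x$end > len[x$chrom]
  if (any(over)) {
    abort(sprintf("%s extend beyond chromosome length on: %s",
                  what, paste(unique(x$chrom[over]), collapse = ", ")))
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    abort(sprintf("%s must satisfy 0 <= start < end", what))
  }
  invisible(x)
}
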