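# Binned signal tracks: fixed-width per-chromosome value vectors with a
# missing-data mask (NA). This is the shared container for Repli-seq
# early/late counts, RT log-ratios and nascent-RNA densities.

#' Bin an interval table of values into a fixed-width track
#'
#' Values are averaged into bins with length weighting: a record
#' contributes to each bin it overlaps in proportion to the overlapped
#' bp. Uncovered sub-bin stretches carry no weight (they are excluded,
#' not zero-filled), and completely uncovered bins are masked (`NA`).
#'
#' @param intervals tibble with columns `chrom`, `start`, `end`, `value`.
#' @param genome a genome table.
#' @param bin_size bin width in bp.
#' @return A binned track: the [tile_genome()] frame plus a `value` column.
#' @export
bin_values <- function(intervals, genome, bin_size) {
  assert_columns(intervals, c("chrom", "start", "end", "value"), "intervals")
  check_intervals_in_genome(intervals, genome, "bedGraph records")
  frame <- tile_genome(genome, bin_size)
  if (nrow(intervals) == 0) return(mutate(frame, value = NA_real_))
  first_bin <- intervals$start %/% bin_size
  last_bin <- (intervals$end - 1) %/% bin_size
  nb <- last_bin - first_bin + 1
  ridx <- rep(seq_len(nrow(intervals)), nb)
  bin <- unlist(purrr::map2(first_bin, last_bin, seq), use.names = FALSE)
  ov_start <- pmax(intervals$start[ridx], bin * bin_size)
  ov_end <- pmin(intervals$end[ridx], (bin + 1) * bin_size)
  w <- ov_end - ov_start
  agg <- tibble(chrom = intervals$chrom[ridx], bin = as.integer(bin),
                wv = w * intervals$value[ridx], w = w) %>%
    group_by(.data$chrom, .data$bin) %>%
    summarise(value = sum(.data$wv) / sum(.data$w), .groups = "drop")
  frame %>% left_join(agg, by = c("chrom", "bin"))
}

#' Read a 4-column bedGraph into a binned track
#'
#' Records may be unsorted and need not align with bin edges; they are
#' length-weight averaged into `bin_size` bins ([bin_values()]). Track
#' definition lines and `#` comments are skipped.
#'
#' @param path path to a UCSC 4-column bedGraph file.
#' @param genome a genome table; records on unknown chromosomes or past
#'   chromosome ends are rejected.
#' @param bin_size bin width in bp.
#' @return A binned track tibble (`chrom`, `start`, `end`, `bin`, `value`);
#'   uncovered bins are `NA`.
#' @export
read_bedgraph <- function(path, genome, bin_size) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warn(sprintf("'%s' contains no data records.", path))
    return(bin_values(tibble(chrom = character(), start = numeric(),
                             end = numeric(), value = numeric()),
                      genome, bin_size))
  }
  fields <- stringr::str_split_fixed(lines, "\\s+", 5)
  bad <- fields[, 4] == "" | fields[, 5] != ""
  suppressWarnings({
    start <- as.numeric(fields[, 2])
    end <- as.numeric(fields[, 3])
    value <- as.numeric(fields[, 4])
  })
  bad <- bad | is.na(start) | is.na(end) | is.na(value)
  if (any(bad)) {
    abort(sprintf("Malformed bedGraph record in '%s' at line %d: '%s'",
                  path, lineno[which(bad)[1]], lines[which(bad)[1]]))
  }
  bin_values(tibble(chrom = fields[, 1], start = start, end = end,
                    value = value),
             genome, bin_size)
}

#' Write a binned track as bedGraph
#'
#' Masked bins are omitted. Values are written with shortest
#' round-trip formatting, so a write/read cycle at the same bin size
#' reproduces the track exactly.
#'
#' @param track a binned track tibble.
#' @param path output path.
#' @param value_col name of the value column to write.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value_col = "value") {
  assert_columns(track, c("chrom", "start", "end", value_col), "track")
  out <- track %>%
    filter(!is.na(.data[[value_col]])) %>%
    arrange(.data$chrom, .data$start) %>%
    select("chrom", "start", "end", dplyr::all_of(value_col))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
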