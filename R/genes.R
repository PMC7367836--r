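# Gene annotation input and generic interval output.

#' Read a gene annotation into a gene table
#'
#' BED input (6 or 12 columns) is taken as one gene per record; minimal
#' GTF input (gene/transcript/exon features with a `gene_id` attribute,
#' 1-based inclusive coordinates) is collapsed to the union span per
#' gene identifier. Multi-isoform genes are therefore represented by
#' their union span, the convention used for all gene-length
#' classification downstream.
#'
#' @param path annotation file path.
#' @param format `"bed"` (BED6/BED12, name column = gene id) or
#'   `"gtf-minimal"`.
#' @return A gene table: tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `length` (bp, end - start). 0-based half-open.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gtf-minimal")) {
  format <- match.arg(format)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(sprintf("'%s' contains no gene records.", path))
    return(tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  strand = character(), length = numeric()))
  }
  if (format == "bed") {
    f <- stringr::str_split_fixed(lines, "\t", 13)
    if (any(f[, 3] == "")) abort(sprintf("'%s': BED needs >= 3 columns.", path))
    genes <- tibble(
      gene_id = ifelse(f[, 4] == "", paste0("gene_", seq_along(lines)), f[, 4]),
      chrom = f[, 1],
      start = as.numeric(f[, 2]),
      end = as.numeric(f[, 3]),
      strand = ifelse(f[, 6] %in% c("+", "-"), f[, 6], ".")
    )
    if (anyDuplicated(genes$gene_id)) {
      abort(sprintf("Duplicate gene id(s) in '%s': %s", path,
                    paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                          collapse = ", ")))
    }
  } else {
    f <- stringr::str_split_fixed(lines, "\t", 9)
    if (any(f[, 9] == "")) abort(sprintf("'%s': GTF needs 9 columns.", path))
    gid <- stringr::str_match(f[, 9], 'gene_id[ =]+"?([^";]+)"?')[, 2]
    if (any(is.na(gid))) {
      abort(sprintf("GTF record without gene_id in '%s' (line %d)",
                    path, which(is.na(gid))[1]))
    }
    genes <- tibble(gene_id = gid, chrom = f[, 1],
                    start = as.numeric(f[, 4]) - 1,   # 1-based -> 0-based
                    end = as.numeric(f[, 5]),
                    strand = ifelse(f[, 7] %in% c("+", "-"), f[, 7], ".")) %>%
      group_by(.data$gene_id) %>%
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), strand = first(.data$strand),
                .groups = "drop")
  }
  if (any(is.na(genes$start) | is.na(genes$end))) {
    abort(sprintf("Non-numeric coordinates in '%s'.", path))
  }
  if (any(genes$end <= genes$start)) {
    abort(sprintf("Zero- or negative-length gene(s) in '%s': %s", path,
                  paste(genes$gene_id[genes$end <= genes$start], collapse = ", ")))
  }
  genes %>%
    mutate(length = .data$end - .data$start) %>%
    arrange(.data$chrom, .data$start) %>%
    select("gene_id", "chrom", "start", "end", "strand", "length")
}

#' Write an interval table as BED or TSV
#'
#' BED output is 0-based half-open, tab-separated and sorted by
#' (chrom, start); optional `name`, `score` and `strand` columns are
#' used when present. TSV output carries a header and all columns.
#'
#' @param records tibble with at least `chrom`, `start`, `end`.
#' @param path output path.
#' @param format `"bed"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_interval_table <- function(records, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  assert_columns(records, c("chrom", "start", "end"), "records")
  if (format == "tsv") {
    out <- records %>%
      mutate(across(dplyr::where(is.list), ~ map_chr(.x, paste, collapse = ","))) %>%
      arrange(.data$chrom, .data$start)
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(path))
  }
  out <- records %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(
      name = if ("name" %in% names(records)) .data$name else ".",
      score = if ("score" %in% names(records)) {
        pmin(pmax(round_half_up(.data$score), 0), 1000)
      } else 0,
      strand = if ("strand" %in% names(records)) .data$strand else "."
    ) %>%
    select("chrom", "start", "end", "name", "score", "strand")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
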