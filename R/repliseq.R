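# Replication-timing (RT) profiles from early/late S-phase read counts.
#
# RT is measured as log2(early/late) per fixed-width bin (5 kb by
# default throughout the package); positive values mean early
# replication. Profiles from several samples are kept in one long
# tibble keyed by (chrom, start, end, sample, condition, replicate).

#' Compute an RT profile from early and late count tracks
#'
#' RT = log2((early + pseudocount) / (late + pseudocount)) per bin.
#' Bins whose combined early + late coverage falls below `min_coverage`
#' are masked: a log-ratio over a handful of reads is dominated by
#' sampling noise and would blow up in read-poor deserts.
#'
#' @param early,late binned count tracks on the same genome and bin
#'   size (tibbles with `chrom`, `start`, `end`, `value`).
#' @param pseudocount reads added to both fractions (default 1).
#' @param min_coverage minimum early + late reads per bin (default 10).
#' @param sample_id sample label.
#' @param condition `"control"` or `"APH"`.
#' @param replicate replicate index.
#' @return An RT profile tibble: `chrom`, `start`, `end`, `sample`,
#'   `condition`, `replicate`, `rt` (`NA` = masked).
#' @export
compute_rt_profile <- function(early, late, pseudocount = 1, min_coverage = 10,
                               sample_id = "sample1",
                               condition = c("control", "APH"),
                               replicate = 1L) {
  condition <- match.arg(condition)
  assert_columns(early, c("chrom", "start", "end", "value"), "early")
  assert_columns(late, c("chrom", "start", "end", "value"), "late")
  if (nrow(early) != nrow(late) ||
      !all(early$chrom == late$chrom & early$start == late$start &
             early$end == late$end)) {
    abort("`early` and `late` must share genome, bin size and bin frame.")
  }
  e <- early$value
  l <- late$value
  if (any(e < 0, na.rm = TRUE) || any(l < 0, na.rm = TRUE)) {
    abort("Read counts must be non-negative.")
  }
  rt <- log2((e + pseudocount) / (l + pseudocount))
  rt[is.na(e) | is.na(l) | (e + l) < min_coverage] <- NA_real_
  tibble(chrom = early$chrom, start = early$start, end = early$end,
         sample = sample_id, condition = condition,
         replicate = as.integer(replicate), rt = rt)
}

rt_wide <- function(profiles) {
  assert_columns(profiles, c("chrom", "start", "end", "sample", "rt"),
                 "profiles")
  profiles %>%
    select("chrom", "start", "end", "sample", "rt") %>%
    pivot_wider(names_from = "sample", values_from = "rt") %>%
    arrange(.data$chrom, .data$start)
}

sample_meta <- function(profiles) {
  profiles %>%
    distinct(.data$sample, .data$condition, .data$replicate) %>%
    arrange(.data$sample)
}

#' Quantile-normalize RT profiles across samples
#'
#' Replaces each profile's values on jointly unmasked bins by the
#' rank-matched mean quantile across all profiles (classic quantile
#' normalization, computed with \code{limma::normalizeQuantiles}), so
#' all samples share one genome-wide RT distribution while each
#' sample's bin ranking is preserved. Bins masked in any sample are
#' masked in all outputs.
#'
#' @param profiles long RT profile tibble covering >= 2 samples.
#' @return The profiles tibble with `rt` replaced by normalized values.
#' @export
quantile_normalize <- function(profiles) {
  wide <- rt_wide(profiles)
  samples <- setdiff(names(wide), c("chrom", "start", "end", "bin"))
  if (length(samples) < 2) abort("Quantile normalization needs >= 2 profiles.")
  mat <- as.matrix(wide[samples])
  joint <- stats::complete.cases(mat)
  norm <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  if (sum(joint) > 0) {
    norm[joint, ] <- limma::normalizeQuantiles(mat[joint, , drop = FALSE])
  }
  long <- bind_cols(wide[c("chrom", "start", "end")], as_tibble(norm)) %>%
    pivot_longer(dplyr::all_of(samples), names_to = "sample",
                 values_to = "rt")
  meta <- sample_meta(profiles)
  long %>%
    inner_join(meta, by = "sample") %>%
    select("chrom", "start", "end", "sample", "condition", "replicate", "rt") %>%
    arrange(.data$sample, .data$chrom, .data$start)
}

#' Smooth RT profiles along the genome
#'
#' Gaussian kernel smoothing per chromosome and sample over unmasked
#' runs; masked bins neither contribute nor receive values (see
#' [gauss_smooth()]). `sigma_bins = 0` returns the input unchanged.
#'
#' @param profile RT profile tibble (one or more samples).
#' @param sigma_bins kernel standard deviation in bins.
#' @return The profile tibble with smoothed `rt`.
#' @export
smooth_profile <- function(profile, sigma_bins) {
  assert_columns(profile, c("chrom", "start", "rt"), "profile")
  grp <- intersect(c("sample", "chrom"), names(profile))
  profile %>%
    group_by(across(dplyr::all_of(grp))) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(rt = gauss_smooth(.data$rt, sigma_bins)) %>%
    ungroup()
}

#' Correlate RT profiles and project samples
#'
#' Pairwise Pearson correlations over jointly unmasked bins, plus the
#' first two principal components of the sample-by-bin matrix (bin-wise
#' mean-centered). This reproduces the standard replicate-concordance /
#' condition-separation display for genome-wide RT programs.
#'
#' @param profiles long RT profile tibble, >= 2 samples.
#' @return An object of class `rt_correlation` with elements `cor`
#'   (correlation matrix; `NA` where a profile is constant), `scores`
#'   (per-sample tibble with `PC1`, `PC2`), `sdev` (all PC standard
#'   deviations), `n_bins`. Has [tidy()] and [autoplot_rt_pca()]
#'   support.
#' @export
correlate_profiles <- function(profiles) {
  wide <- rt_wide(profiles)
  samples <- setdiff(names(wide), c("chrom", "start", "end", "bin"))
  if (length(samples) < 2) abort("Need >= 2 profiles.")
  mat <- as.matrix(wide[samples])
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 2) abort("Fewer than 2 jointly unmasked bins.")
  const <- apply(mat, 2, function(v) sd(v) == 0)
  cm <- suppressWarnings(cor(mat))
  if (any(const)) {
    warn(sprintf("Constant profile(s): %s; correlations reported as NA.",
                 paste(samples[const], collapse = ", ")))
    cm[const, ] <- NA_real_
    cm[, const] <- NA_real_
  }
  diag(cm) <- ifelse(const, NA_real_, 1)
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  meta <- sample_meta(profiles)
  scores <- tibble(sample = samples,
                   PC1 = pc$x[, 1],
                   PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0) %>%
    inner_join(meta, by = "sample")
  structure(list(cor = cm, scores = scores, sdev = pc$sdev,
                 n_bins = nrow(mat)),
            class = "rt_correlation")
}

#' @export
print.rt_correlation <- function(x, ...) {
  cat(sprintf("RT correlation over %d jointly unmasked bins, %d samples\n",
              x$n_bins, ncol(x$cor)))
  print(round(x$cor, 3))
  invisible(x)
}

#' Average RT profiles within condition
#'
#' @param profiles long RT profile tibble.
#' @return Tibble `chrom`, `start`, `end`, `condition`, `rt` (mean over
#'   replicates; bins masked in every replicate stay `NA`).
#' @export
condition_mean_rt <- function(profiles) {
  profiles %>%
    group_by(.data$chrom, .data$start, .data$end, .data$condition) %>%
    summarise(rt = if (all(is.na(.data$rt))) NA_real_ else
      mean(.data$rt, na.rm = TRUE), .groups = "drop") %>%
    arrange(.data$condition, .data$chrom, .data$start)
}

#' Per-bin RT change under treatment
#'
#' @param profiles long RT profile tibble with both conditions.
#' @param treatment,reference condition labels.
#' @return Tibble `chrom`, `start`, `end`, `delta` = mean(treatment) -
#'   mean(reference). Negative delta = delayed replication.
#' @export
rt_delta <- function(profiles, treatment = "APH", reference = "control") {
  cm <- condition_mean_rt(profiles)
  ref <- cm %>% filter(.data$condition == reference)
  trt <- cm %>% filter(.data$condition == treatment)
  if (nrow(ref) == 0 || nrow(trt) == 0) {
    abort("Both conditions must be present in `profiles`.")
  }
  ref %>%
    select("chrom", "start", "end", rt_ref = "rt") %>%
    inner_join(select(trt, "chrom", "start", "end", rt_trt = "rt"),
               by = c("chrom", "start", "end")) %>%
    mutate(delta = .data$rt_trt - .data$rt_ref) %>%
    select("chrom", "start", "end", "delta") %>%
    arrange(.data$chrom, .data$start)
}

#' Trisect the RT program into early, mid and late S phase
#'
#' With `method = "tertiles"` the cut points are the 1/3 and 2/3
#' genome-wide quantiles of unmasked RT values and bins are assigned by
#' rank, so each label covers one third of unmasked bins to within one
#' bin. Early is the top third (most positive RT).
#'
#' @param profile single-track tibble with `chrom`, `start`, `end`, `rt`
#'   (e.g. a condition mean).
#' @param method `"tertiles"` or `"fixed_cuts"`.
#' @param cuts for `"fixed_cuts"`: numeric `c(late_cut, early_cut)` on
#'   the RT scale; `rt >= early_cut` is early, `rt < late_cut` late.
#' @return The input tibble plus a `phase` column in
#'   `c("early","mid","late")` (`NA` on masked bins), with the cut
#'   points in `attr(, "cuts")`.
#' @export
trisect_rt <- function(profile, method = c("tertiles", "fixed_cuts"),
                       cuts = NULL) {
  method <- match.arg(method)
  assert_columns(profile, c("chrom", "start", "end", "rt"), "profile")
  rt <- profile$rt
  ok <- !is.na(rt)
  phase <- rep(NA_character_, length(rt))
  if (method == "fixed_cuts") {
    if (is.null(cuts) || length(cuts) != 2) {
      abort("`fixed_cuts` requires `cuts = c(late_cut, early_cut)`.")
    }
    cuts <- sort(as.numeric(cuts))
    phase[ok] <- dplyr::case_when(rt[ok] >= cuts[2] ~ "early",
                                  rt[ok] < cuts[1] ~ "late",
                                  TRUE ~ "mid")
  } else {
    v <- rt[ok]
    if (length(unique(v)) == 1) {
      warn("All RT values identical; labeling every bin 'mid'.")
      phase[ok] <- "mid"
      cuts <- c(v[1], v[1])
    } else {
      cuts <- unname(quantile(v, c(1 / 3, 2 / 3)))
      ter <- ntile(v, 3)  # rank-based: thirds within one bin
      phase[ok] <- c("late", "mid", "early")[ter]
    }
  }
  out <- mutate(profile, phase = phase)
  attr(out, "cuts") <- c(late_cut = cuts[1], early_cut = cuts[2])
  out
}

#' Metagene RT matrix over size-sorted genes
#'
#' Each gene body is linearly stretched to `body_bins` columns; flanks
#' of `flank_bp` on each side are taken at native bin resolution, so
#' the gene body occupies the same column span in every row. Rows are
#' sorted by gene length, largest first. Flank stretches running past a
#' chromosome end are masked, not an error.
#'
#' @param track single-track tibble (`chrom`, `start`, `end`, plus the
#'   `value_col`), e.g. a condition-mean RT or a delta track.
#' @param genes gene table ([read_gene_annotation()]).
#' @param body_bins number of stretched gene-body columns (default 100).
#' @param flank_bp flank width each side in bp (default 1 Mb).
#' @param value_col name of the value column in `track`.
#' @return An object of class `metagene_matrix`: list with `matrix`
#'   (genes x columns), `genes` (row order), `body_cols`, `flank_cols`,
#'   `bin_size`. `colmeans` via [tidy()]; plot via [autoplot_metagene()].
#' @export
metagene_rt <- function(track, genes, body_bins = 100, flank_bp = 1e6,
                        value_col = "rt") {
  assert_columns(track, c("chrom", "start", "end", value_col), "track")
  assert_columns(genes, c("gene_id", "chrom", "start", "end", "length"),
                 "genes")
  bin_size <- max(track$end - track$start)
  if (any(genes$length < bin_size)) {
    abort("All genes must be at least one bin long.")
  }
  flank_cols <- as.integer(round_half_up(flank_bp / bin_size))
  genes <- arrange(genes, desc(.data$length))
  track <- arrange(track, .data$chrom, .data$start)
  by_chrom <- split(track, track$chrom)
  ncol_total <- body_bins + 2 * flank_cols
  m <- matrix(NA_real_, nrow(genes), ncol_total,
              dimnames = list(genes$gene_id, NULL))
  for (g in seq_len(nrow(genes))) {
    tr <- by_chrom[[genes$chrom[g]]]
    if (is.null(tr)) next
    centers <- (tr$start + tr$end) / 2
    vals <- tr[[value_col]]
    gs <- genes$start[g]; ge <- genes$end[g]
    # gene body: sample body_bins points at stretched positions
    pos <- gs + (seq_len(body_bins) - 0.5) / body_bins * (ge - gs)
    ok <- !is.na(vals)
    if (sum(ok) >= 2) {
      body <- approx(centers[ok], vals[ok], xout = pos, rule = 2)$y
    } else {
      body <- rep(NA_real_, body_bins)
    }
    # flanks at native resolution
    first_bin <- gs %/% bin_size
    last_bin <- (ge - 1) %/% bin_size
    nbins_chr <- nrow(tr)
    lf <- (first_bin - flank_cols):(first_bin - 1) + 1
    rf <- (last_bin + 1):(last_bin + flank_cols) + 1
    lf[lf < 1 | lf > nbins_chr] <- NA_integer_
    rf[rf < 1 | rf > nbins_chr] <- NA_integer_
    left <- vals[lf]
    right <- vals[rf]
    m[g, ] <- c(left, body, right)
  }
  structure(list(matrix = m, genes = genes,
                 body_cols = (flank_cols + 1):(flank_cols + body_bins),
                 flank_cols = flank_cols, bin_size = bin_size),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("Metagene matrix: %d genes x %d columns (%d body, %d per flank)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$body_cols),
              x$flank_cols))
  invisible(x)
}
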