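# The multilayer fragility signature: a TAD boundary overlapping a
# highly transcribed large gene with APH-induced RT delay. The V-shaped
# RT-delay profile localizes the candidate core fragility region (CFR).

# two-segment (hinge) least-squares fit of a V over the gene body:
# for each candidate vertex, fit value ~ a + bL*(v - x)+ + bR*(x - v)+
# and keep the vertex with minimum RSS. Returns vertex index and the
# fitted value at the vertex. Uses every body bin, so the vertex
# estimate is far less noise-sensitive than a smoothed argmin.
fit_v_vertex <- function(x, y, body) {
  ok <- body[!is.na(y[body])]
  if (length(ok) < 3) return(NULL)
  best_v <- NULL
  best_rss <- Inf
  best_depth <- NA_real_
  for (vi in ok) {
    v <- x[vi]
    basis <- cbind(1, pmax(v - x[ok], 0), pmax(x[ok] - v, 0))
    f <- stats::lm.fit(basis, y[ok])
    rss <- sum(f$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_v <- vi
      best_depth <- unname(f$coefficients[1])
    }
  }
  list(vi = best_v, depth = best_depth)
}

#' Detect a V-shaped RT delay over a gene
#'
#' Operates on the per-bin RT change (APH minus control) across the
#' gene body plus flanks, relative to the flank reference level (median
#' delta over the flanks). The vertex — the most delayed point of the
#' underlying profile inside the gene body — is located either by a
#' two-segment piecewise-linear least-squares fit (`method = "fit"`,
#' the default: robust to bin noise around the flat V bottom) or as the
#' argmin of the Gaussian-smoothed profile (`method = "argmin"`). A V
#' is called when the vertex depth reaches `-min_depth` and the
#' smoothed profile rises by at least `min_depth / 2` on both sides
#' within the searched span. The CFR is the contiguous run of bins
#' around the vertex at least as delayed as `cfr_fraction` of the
#' vertex depth.
#'
#' @param delta_track tibble `chrom`, `start`, `end`, `delta` covering
#'   the searched span (gene plus flanks) at bin resolution.
#' @param gene one-row gene table (or list) with `gene_id`, `chrom`,
#'   `start`, `end`.
#' @param sigma_bins smoothing kernel SD in bins (default 2).
#' @param min_depth minimum V depth in RT units (default 0.5).
#' @param cfr_fraction CFR depth fraction (default 0.8).
#' @param method `"fit"` (hinge fit) or `"argmin"`.
#' @return One-row tibble: `gene_id`, `vertex` (bp, bin center),
#'   `depth` (<= 0 for a called V), `is_v`, `cfr_start`, `cfr_end`,
#'   `left_rise`, `right_rise`.
#' @export
detect_v_shape <- function(delta_track, gene, sigma_bins = 2,
                           min_depth = 0.5, cfr_fraction = 0.8,
                           method = c("fit", "argmin")) {
  method <- match.arg(method)
  assert_columns(delta_track, c("chrom", "start", "end", "delta"),
                 "delta_track")
  tr <- delta_track %>%
    filter(.data$chrom == gene$chrom) %>%
    arrange(.data$start)
  body <- which(tr$start < gene$end & tr$end > gene$start)
  if (length(body) < 3) abort("Gene must span at least 3 bins.")
  sm <- gauss_smooth(tr$delta, sigma_bins)
  flank <- setdiff(seq_len(nrow(tr)), body)
  ref <- if (length(flank) > 0 && any(!is.na(sm[flank]))) {
    median(sm[flank], na.rm = TRUE)
  } else 0
  rel <- sm - ref
  if (all(is.na(rel[body]))) {
    return(tibble(gene_id = gene$gene_id, vertex = NA_real_,
                  depth = NA_real_, is_v = FALSE, cfr_start = NA_real_,
                  cfr_end = NA_real_, left_rise = NA_real_,
                  right_rise = NA_real_))
  }
  if (method == "fit") {
    centers <- (tr$start + tr$end) / 2
    fit <- fit_v_vertex(centers, tr$delta - ref, body)
  } else {
    fit <- NULL
  }
  if (is.null(fit)) {
    vi <- body[which.min(rel[body])]
    depth <- rel[vi]
  } else {
    vi <- fit$vi
    depth <- min(fit$depth, 0)
  }
  left_rise <- if (vi > 1) max(rel[1:(vi - 1)], na.rm = TRUE) - depth else 0
  right_rise <- if (vi < nrow(tr)) {
    max(rel[(vi + 1):nrow(tr)], na.rm = TRUE) - depth
  } else 0
  is_v <- is.finite(depth) && depth <= -min_depth &&
    left_rise >= min_depth / 2 && right_rise >= min_depth / 2
  # CFR: contiguous bins around the vertex with rel <= cfr_fraction * depth
  thr <- depth * cfr_fraction
  lo <- vi
  while (lo > 1 && !is.na(rel[lo - 1]) && rel[lo - 1] <= thr) lo <- lo - 1
  hi <- vi
  while (hi < nrow(tr) && !is.na(rel[hi + 1]) && rel[hi + 1] <= thr) hi <- hi + 1
  tibble(gene_id = gene$gene_id,
         vertex = (tr$start[vi] + tr$end[vi]) / 2,
         depth = depth, is_v = is_v,
         cfr_start = tr$start[lo], cfr_end = tr$end[hi],
         left_rise = left_rise, right_rise = right_rise)
}

#' Flag genes overlapping APH-delayed regions
#'
#' @param genes gene table.
#' @param regions region tibble from [merge_contiguous()].
#' @return Tibble `gene_id`, `is_rt_delayed` (>= 1 delayed region
#'   overlaps the gene body), `delay_magnitude` (most negative
#'   overlapping delayed-region mean delta; `NA` when none),
#'   `region_ids` (list column).
#' @export
gene_rt_delay <- function(genes, regions) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "genes")
  del <- regions %>% filter(.data$direction == "delayed")
  hits <- overlap_pairs(genes, del)
  ids <- vector("list", nrow(genes))
  mag <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) ids[[i]] <- character()
  if (nrow(hits) > 0) {
    sp <- split(hits$idx_y, hits$idx_x)
    gi <- as.integer(names(sp))
    ids[gi] <- lapply(sp, function(j) del$region_id[j])
    mag[gi] <- vapply(sp, function(j) min(del$mean_delta[j]), numeric(1))
  }
  tibble(gene_id = genes$gene_id, is_rt_delayed = lengths(ids) > 0,
         delay_magnitude = mag, region_ids = ids)
}

#' Assemble per-gene evidence for the fragility signature
#'
#' Joins the component classifications on gene id; any gene missing
#' from a component table is an error (the signature is a conjunction
#' and must be evaluated on one gene set).
#'
#' @param genes gene table.
#' @param sizes [classify_sizes()] output.
#' @param expression [classify_quartiles()] output.
#' @param architecture [classify_gene_architecture()] output.
#' @param delay [gene_rt_delay()] output.
#' @return Gene table joined with all component columns.
#' @export
assemble_gene_evidence <- function(genes, sizes, expression, architecture,
                                   delay) {
  for (comp in list(sizes = sizes, expression = expression,
                    architecture = architecture, delay = delay)) {
    missing <- setdiff(genes$gene_id, comp$gene_id)
    if (length(missing) > 0) {
      abort(sprintf("Component table missing gene id(s): %s",
                    paste(head(missing, 10), collapse = ", ")))
    }
  }
  genes %>%
    left_join(select(sizes, "gene_id", "size_class", "large_subgroup",
                     "is_large"), by = "gene_id") %>%
    left_join(select(expression, "gene_id", "density", "quartile",
                     "expressed", "highly_transcribed"), by = "gene_id") %>%
    left_join(select(architecture, "gene_id", "spans_boundary",
                     "boundary_ids"), by = "gene_id") %>%
    left_join(select(delay, "gene_id", "is_rt_delayed", "delay_magnitude",
                     "region_ids"), by = "gene_id")
}

#' Call the multilayer fragility signature
#'
#' A gene is a fragile-site candidate iff it is large (> 300 kb by
#' default upstream), highly transcribed (expression quartile q3 or
#' q4), RT-delayed under APH, and spans a TAD boundary. All four
#' components are reported independently alongside the verdict, and the
#' intermediate cohort sizes (large; large & transcribed; large &
#' transcribed & delayed; all four) are kept as the screening funnel.
#'
#' @param evidence per-gene evidence table from
#'   [assemble_gene_evidence()] (needs `is_large`,
#'   `highly_transcribed`, `is_rt_delayed`, `spans_boundary`).
#' @return An object of class `fragility_calls`: the evidence tibble
#'   plus `fragile_candidate`, with the funnel in `attr(, "funnel")`
#'   (also via [fragility_funnel()]).
#' @export
call_fragility_signature <- function(evidence) {
  assert_columns(evidence, c("gene_id", "is_large", "highly_transcribed",
                             "is_rt_delayed", "spans_boundary"), "evidence")
  calls <- evidence %>%
    mutate(fragile_candidate = .data$is_large & .data$highly_transcribed &
             .data$is_rt_delayed & .data$spans_boundary)
  funnel <- tibble(
    cohort = c("large", "large_transcribed", "large_transcribed_delayed",
               "fragile_candidate"),
    n = c(sum(calls$is_large),
          sum(calls$is_large & calls$highly_transcribed),
          sum(calls$is_large & calls$highly_transcribed &
                calls$is_rt_delayed),
          sum(calls$fragile_candidate)))
  structure(calls, class = c("fragility_calls", class(calls)),
            funnel = funnel)
}

#' Screening funnel of a fragility call set
#'
#' @param calls a `fragility_calls` object.
#' @return Tibble of cohort sizes from large genes down to the final
#'   candidates.
#' @export
fragility_funnel <- function(calls) {
  f <- attr(calls, "funnel")
  if (is.null(f)) abort("`calls` must come from call_fragility_signature().")
  f
}

#' Localize candidate core fragility regions
#'
#' Runs [detect_v_shape()] on every fragile candidate (or every
#' RT-delayed gene when `all_delayed = TRUE`) against a genome-wide
#' delta track.
#'
#' @param calls `fragility_calls` object.
#' @param delta genome-wide delta track ([rt_delta()]).
#' @param genes gene table (coordinates for the candidates).
#' @param flank_bp search flank each side (default 500 kb).
#' @param sigma_bins,min_depth,cfr_fraction see [detect_v_shape()].
#' @param all_delayed analyse all RT-delayed genes, not only candidates.
#' @return Tibble of [detect_v_shape()] rows, one per analysed gene.
#' @export
locate_cfr <- function(calls, delta, genes, flank_bp = 5e5, sigma_bins = 2,
                       min_depth = 0.5, cfr_fraction = 0.8,
                       all_delayed = FALSE) {
  target_ids <- if (all_delayed) {
    calls$gene_id[calls$is_rt_delayed]
  } else {
    calls$gene_id[calls$fragile_candidate]
  }
  tg <- genes %>% filter(.data$gene_id %in% target_ids)
  if (nrow(tg) == 0) {
    return(tibble(gene_id = character(), vertex = numeric(),
                  depth = numeric(), is_v = logical(),
                  cfr_start = numeric(), cfr_end = numeric(),
                  left_rise = numeric(), right_rise = numeric()))
  }
  purrr::map(seq_len(nrow(tg)), function(i) {
    g <- tg[i, ]
    span <- delta %>%
      filter(.data$chrom == g$chrom, .data$end > g$start - flank_bp,
             .data$start < g$end + flank_bp)
    detect_v_shape(span, g, sigma_bins = sigma_bins, min_depth = min_depth,
                   cfr_fraction = cfr_fraction)
  }) %>% bind_rows()
}
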