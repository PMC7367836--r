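# APH-responsive RT windows, differentially replicated regions and RT
# signatures.
#
# The genome is segmented into fixed windows (100 kb by default); a
# window is RT-variable when the APH-vs-control change exceeds a
# threshold calibrated as two standard deviations of technical-replicate
# differences (~1 RT unit). Contiguous same-direction windows merge into
# differentially replicated regions, and k-means over the window-by-
# sample RT matrix yields RT signatures (e.g. early-replicating regions
# delayed by APH).

#' Mean RT per fixed window, per sample
#'
#' Windows with more than `max_masked_frac` of their bins masked in the
#' jointly unmasked sense (masked in any sample) are excluded.
#'
#' @param profiles long RT profile tibble.
#' @param window window width in bp (default 100 kb); must be a
#'   multiple of the bin size.
#' @param max_masked_frac maximum tolerated masked-bin fraction.
#' @return Tibble `chrom`, `start`, `end`, `sample`, `condition`,
#'   `replicate`, `rt` (window mean over jointly unmasked bins).
#' @export
window_rt <- function(profiles, window = 1e5, max_masked_frac = 0.5) {
  assert_columns(profiles, c("chrom", "start", "end", "sample", "rt"),
                 "profiles")
  bin_size <- max(profiles$end - profiles$start)
  if (window %% bin_size != 0) {
    abort(sprintf("`window` (%g) must be a multiple of the bin size (%g).",
                  window, bin_size))
  }
  joint <- profiles %>%
    group_by(.data$chrom, .data$start, .data$end) %>%
    summarise(joint_ok = !any(is.na(.data$rt)), .groups = "drop")
  profiles %>%
    inner_join(joint, by = c("chrom", "start", "end")) %>%
    mutate(wstart = (.data$start %/% window) * window) %>%
    group_by(.data$chrom, .data$wstart, .data$sample, .data$condition,
             .data$replicate) %>%
    summarise(
      masked_frac = mean(!.data$joint_ok),
      rt = if (any(.data$joint_ok))
        mean(.data$rt[.data$joint_ok]) else NA_real_,
      .groups = "drop") %>%
    filter(.data$masked_frac <= max_masked_frac, !is.na(.data$rt)) %>%
    mutate(end = .data$wstart + window) %>%
    select("chrom", start = "wstart", "end", "sample", "condition",
           "replicate", "rt") %>%
    arrange(.data$sample, .data$chrom, .data$start)
}

#' Calibrate the RT-variability threshold from technical replicates
#'
#' Pools per-window RT differences over all within-condition replicate
#' pairs and returns twice their standard deviation — the calibration
#' behind the conventional 1-RT-unit cutoff (replicate noise of about
#' 0.35 RT units gives pairwise-difference SD ~0.5 and threshold ~1).
#'
#' @param profiles long RT profile tibble for ONE condition, >= 2
#'   replicates.
#' @param window window width in bp.
#' @return One-row tibble: `threshold` (2 x SD), `sd_pairwise`,
#'   `n_windows`, `n_pairs`, `fallback` (the fixed 1.0 RT-unit default).
#' @export
estimate_variability_threshold <- function(profiles, window = 1e5) {
  conds <- unique(profiles$condition)
  if (length(conds) > 1) {
    abort("Supply replicates of a single condition.")
  }
  samples <- unique(profiles$sample)
  if (length(samples) < 2) {
    abort(paste("Need >= 2 technical replicates to calibrate;",
                "use the fixed threshold of 1.0 RT units instead."))
  }
  w <- window_rt(profiles, window = window) %>%
    select("chrom", "start", "sample", "rt") %>%
    pivot_wider(names_from = "sample", values_from = "rt")
  mat <- as.matrix(w[samples])
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  pairs <- utils::combn(length(samples), 2)
  diffs <- unlist(lapply(seq_len(ncol(pairs)), function(j) {
    mat[, pairs[1, j]] - mat[, pairs[2, j]]
  }))
  s <- sd(diffs)
  tibble(threshold = 2 * s, sd_pairwise = s, n_windows = nrow(mat),
         n_pairs = ncol(pairs), fallback = 1.0)
}

#' Detect RT-variable windows between control and APH
#'
#' A window is flagged when the condition-mean RT change reaches the
#' threshold in magnitude AND every cross-condition replicate pair
#' agrees on the sign of the change (suppressing single-replicate
#' artifacts). `mode = "any_pair"` instead requires some replicate pair
#' to reach the threshold (with the same sign-consistency rule).
#'
#' @param profiles long RT profile tibble with both conditions.
#' @param window window width in bp (default 100 kb).
#' @param threshold minimum |delta| in RT units (default 1.0).
#' @param mode `"condition_mean"` (default) or `"any_pair"`.
#' @param treatment,reference condition labels.
#' @return Tibble of windows: `chrom`, `start`, `end`, per-sample RT
#'   columns, `mean_ctrl`, `mean_aph`, `delta`, `sign_consistent`,
#'   `flagged`, `direction` (`"delayed"`/`"advanced"`/`NA`). Sample
#'   metadata in `attr(, "samples")`.
#' @export
detect_variable_windows <- function(profiles, window = 1e5, threshold = 1.0,
                                    mode = c("condition_mean", "any_pair"),
                                    treatment = "APH", reference = "control") {
  mode <- match.arg(mode)
  wr <- window_rt(profiles, window = window)
  meta <- sample_meta(profiles)
  ctrl_samples <- meta$sample[meta$condition == reference]
  aph_samples <- meta$sample[meta$condition == treatment]
  if (length(ctrl_samples) == 0 || length(aph_samples) == 0) {
    abort("Need >= 1 replicate per condition.")
  }
  wide <- wr %>%
    select("chrom", "start", "end", "sample", "rt") %>%
    pivot_wider(names_from = "sample", values_from = "rt")
  keep <- stats::complete.cases(wide[c(ctrl_samples, aph_samples)])
  wide <- wide[keep, , drop = FALSE]
  cm <- as.matrix(wide[ctrl_samples])
  am <- as.matrix(wide[aph_samples])
  mean_ctrl <- rowMeans(cm)
  mean_aph <- rowMeans(am)
  delta <- mean_aph - mean_ctrl
  # sign consistency across all cross-condition pairs:
  # all aph - ctrl differences share a sign iff the condition value
  # ranges do not interleave
  max_a <- apply(am, 1, max); min_a <- apply(am, 1, min)
  max_c <- apply(cm, 1, max); min_c <- apply(cm, 1, min)
  sign_consistent <- (max_a < min_c) | (min_a > max_c)
  if (mode == "condition_mean") {
    flagged <- abs(delta) >= threshold & sign_consistent
  } else {
    pair_max <- pmax(abs(max_a - min_c), abs(min_a - max_c))
    flagged <- pair_max >= threshold & sign_consistent
  }
  out <- wide %>%
    mutate(mean_ctrl = mean_ctrl, mean_aph = mean_aph, delta = delta,
           sign_consistent = sign_consistent, flagged = flagged,
           direction = dplyr::case_when(!flagged ~ NA_character_,
                                        delta < 0 ~ "delayed",
                                        TRUE ~ "advanced")) %>%
    arrange(.data$chrom, .data$start)
  attr(out, "samples") <- meta
  out
}

#' Merge contiguous flagged windows into differentially replicated regions
#'
#' Maximal runs of genomically adjacent flagged windows on the same
#' chromosome with the same direction are merged; delayed and advanced
#' runs are never joined.
#'
#' @param windows output of [detect_variable_windows()].
#' @return Region tibble: `region_id`, `chrom`, `start`, `end`,
#'   `direction`, `n_windows`, `mean_delta` (window mean of deltas),
#'   `mean_ctrl`, `window_ids` (list column of member window keys).
#' @export
merge_contiguous <- function(windows) {
  assert_columns(windows, c("chrom", "start", "end", "delta", "flagged",
                            "direction"), "windows")
  fl <- windows %>% filter(.data$flagged) %>%
    arrange(.data$chrom, .data$start)
  if (nrow(fl) == 0) {
    return(tibble(region_id = character(), chrom = character(),
                  start = numeric(), end = numeric(),
                  direction = character(), n_windows = integer(),
                  mean_delta = numeric(), mean_ctrl = numeric(),
                  window_ids = list()))
  }
  fl <- fl %>%
    mutate(new_run = .data$chrom != lag(.data$chrom, default = "") |
             .data$start != lag(.data$end, default = -1) |
             .data$direction != lag(.data$direction, default = ""),
           run = cumsum(.data$new_run))
  fl %>%
    mutate(wid = paste0(.data$chrom, ":", .data$start)) %>%
    group_by(.data$run) %>%
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), direction = first(.data$direction),
              n_windows = n(), mean_delta = mean(.data$delta),
              mean_ctrl = mean(.data$mean_ctrl),
              window_ids = list(.data$wid), .groups = "drop") %>%
    mutate(region_id = sprintf("region_%04d", row_number())) %>%
    select("region_id", "chrom", "start", "end", "direction", "n_windows",
           "mean_delta", "mean_ctrl", "window_ids")
}

#' Cluster RT-variable windows into RT signatures
#'
#' k-means over the flagged-window-by-sample RT matrix (best of
#' `restarts` initializations). Each cluster is auto-labeled from its
#' centroid condition means — e.g. a cluster early in control and
#' mid/late under APH is an "early_delayed" signature — and tested with
#' a paired t-test of control vs APH window means (raw and
#' Benjamini-Hochberg-adjusted p).
#'
#' @param windows output of [detect_variable_windows()] (only flagged
#'   windows are clustered).
#' @param k number of clusters (default 5).
#' @param restarts k-means restarts (default 50).
#' @param seed RNG seed.
#' @param cuts `c(late_cut, early_cut)` on the RT scale used to name
#'   centroid phases (default `c(-0.5, 0.5)`).
#' @param treatment,reference condition labels.
#' @return An object of class `rt_signatures`: list with `windows`
#'   (flagged windows plus `cluster`), `clusters` (per-cluster tibble:
#'   size, centroid condition means, `direction`, `label`, `p_value`,
#'   `p_adj`), `fit` (the kmeans object). [tidy()] returns the
#'   per-cluster table, [glance()] a one-row summary.
#' @export
cluster_rt_signatures <- function(windows, k = 5, restarts = 50, seed = 1,
                                  cuts = c(-0.5, 0.5), treatment = "APH",
                                  reference = "control") {
  meta <- attr(windows, "samples")
  if (is.null(meta)) abort("`windows` must come from detect_variable_windows().")
  fl <- windows %>% filter(.data$flagged)
  if (k < 1) abort("`k` must be >= 1.")
  if (k > nrow(fl)) {
    abort(sprintf("k = %d exceeds the number of flagged windows (%d).",
                  k, nrow(fl)))
  }
  samples <- sort(meta$sample)
  mat <- as.matrix(fl[samples])
  set.seed(seed)
  fit <- kmeans(mat, centers = k, nstart = restarts, iter.max = 100)
  fl$cluster <- fit$cluster
  ctrl_samples <- meta$sample[meta$condition == reference]
  aph_samples <- meta$sample[meta$condition == treatment]
  phase_of <- function(v) {
    dplyr::case_when(v >= cuts[2] ~ "early", v < cuts[1] ~ "late",
                     TRUE ~ "mid")
  }
  clusters <- purrr::map(sort(unique(fl$cluster)), function(cl) {
    sub <- fl[fl$cluster == cl, ]
    ctrl_mean <- mean(as.matrix(sub[ctrl_samples]))
    aph_mean <- mean(as.matrix(sub[aph_samples]))
    direction <- if (aph_mean < ctrl_mean) "delayed" else "advanced"
    p_ctrl <- phase_of(ctrl_mean); p_aph <- phase_of(aph_mean)
    label <- if (p_ctrl == p_aph) {
      paste0("within_", p_ctrl, "_", direction)
    } else {
      paste0(p_ctrl, "_", direction)
    }
    pv <- if (nrow(sub) >= 2) {
      t.test(sub$mean_ctrl, sub$mean_aph, paired = TRUE)$p.value
    } else NA_real_
    tibble(cluster = cl, n_windows = nrow(sub), ctrl_mean = ctrl_mean,
           aph_mean = aph_mean, direction = direction, label = label,
           p_value = pv)
  }) %>% bind_rows() %>%
    mutate(p_adj = p.adjust(.data$p_value, method = "BH"))
  structure(list(windows = fl, clusters = clusters, fit = fit,
                 samples = meta),
            class = "rt_signatures")
}

#' @export
print.rt_signatures <- function(x, ...) {
  cat(sprintf("RT signatures: %d clusters over %d RT-variable windows\n",
              nrow(x$clusters), nrow(x$windows)))
  print(x$clusters)
  invisible(x)
}

#' Overlay RT-variable regions on cytogenetic bands
#'
#' Counts delayed and advanced regions overlapping each band (a region
#' straddling two bands is counted in both) and classifies each band as
#' delayed-only / advanced-only / both / neither. When `cuts` are given
#' and regions carry `mean_ctrl`, each delayed region inside a fragile
#' band is also assigned its control-condition S-phase tercile, giving
#' the composition of delayed fragile-band loci by normal RT.
#'
#' @param regions region tibble ([merge_contiguous()]).
#' @param bands tibble `band_id`, `chrom`, `start`, `end`.
#' @param fragile_band_ids character vector of fragile (CFS) band ids;
#'   must all be present in `bands`.
#' @param cuts optional `c(late_cut, early_cut)` for the control-RT
#'   trisection of delayed loci.
#' @return A `band_annotation` tibble: per band `band_id`, `fragile`,
#'   `n_delayed`, `n_advanced`, `category`; [glance()] summarises the
#'   fragile-band fractions.
#' @export
annotate_bands <- function(regions, bands, fragile_band_ids, cuts = NULL) {
  assert_columns(bands, c("band_id", "chrom", "start", "end"), "bands")
  missing <- setdiff(fragile_band_ids, bands$band_id)
  if (length(missing) > 0) {
    abort(sprintf("Fragile band id(s) not in the band table: %s",
                  paste(missing, collapse = ", ")))
  }
  hits <- overlap_pairs(bands, regions)
  per_band <- bands %>%
    mutate(idx_x = row_number()) %>%
    left_join(hits, by = "idx_x") %>%
    mutate(direction = regions$direction[.data$idx_y]) %>%
    group_by(.data$band_id, .data$chrom, .data$start, .data$end) %>%
    summarise(n_delayed = sum(.data$direction == "delayed", na.rm = TRUE),
              n_advanced = sum(.data$direction == "advanced", na.rm = TRUE),
              .groups = "drop") %>%
    mutate(fragile = .data$band_id %in% fragile_band_ids,
           category = dplyr::case_when(
             .data$n_delayed > 0 & .data$n_advanced > 0 ~ "both",
             .data$n_delayed > 0 ~ "delayed_only",
             .data$n_advanced > 0 ~ "advanced_only",
             TRUE ~ "neither"))
  phase_comp <- NULL
  if (!is.null(cuts) && "mean_ctrl" %in% names(regions) && nrow(hits) > 0) {
    frag <- bands$band_id %in% fragile_band_ids
    del_in_frag <- hits %>%
      filter(frag[.data$idx_x],
             regions$direction[.data$idx_y] == "delayed") %>%
      pull("idx_y") %>% unique()
    if (length(del_in_frag) > 0) {
      v <- regions$mean_ctrl[del_in_frag]
      ph <- dplyr::case_when(v >= cuts[2] ~ "early", v < cuts[1] ~ "late",
                             TRUE ~ "mid")
      phase_comp <- tibble(phase = c("early", "mid", "late")) %>%
        left_join(as_tibble(table(phase = ph)), by = "phase") %>%
        mutate(n = dplyr::coalesce(.data$n, 0L),
               fraction = .data$n / length(ph))
    }
  }
  structure(per_band, class = c("band_annotation", class(per_band)),
            phase_composition = phase_comp)
}
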