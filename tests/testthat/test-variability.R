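# RT-variable windows, region merging, signature clustering and band
# annotation.

test_that("window_rt averages jointly unmasked bins and drops mostly-masked windows", {
  # 2 windows of 4 bins each; bin 2 masked in one sample -> excluded
  # from every sample's window mean (joint mask)
  vals <- list(Ctrl_1 = c(1, 2, 3, 4, 10, 10, 10, 10),
               Ctrl_2 = c(2, NA, 4, 6, 20, 20, 20, 20))
  prof <- make_profiles(vals, bin_size = 25)
  w <- window_rt(prof, window = 100, max_masked_frac = 0.5)
  w1 <- w[w$start == 0, ]
  expect_equal(w1$rt[w1$sample == "Ctrl_1"], mean(c(1, 3, 4)))
  expect_equal(w1$rt[w1$sample == "Ctrl_2"], mean(c(2, 4, 6)))
  # window with 3 of 4 bins masked is dropped entirely
  vals2 <- list(Ctrl_1 = c(1, NA, NA, NA, 5, 5, 5, 5))
  w2 <- window_rt(make_profiles(vals2, bin_size = 25), window = 100)
  expect_equal(w2$start, 100)
  # window must be a bin-size multiple
  expect_error(window_rt(prof, window = 110), "multiple")
})

test_that("threshold calibration returns twice the replicate pairwise-difference SD", {
  set.seed(21)
  n <- 3000
  base <- rnorm(n, 0, 1.5)
  s <- 0.4  # target pairwise SD
  vals <- list(Ctrl_1 = base + rnorm(n, 0, s / sqrt(2)),
               Ctrl_2 = base + rnorm(n, 0, s / sqrt(2)))
  prof <- make_profiles(vals, bin_size = 1000)
  est <- estimate_variability_threshold(prof, window = 1000)
  expect_equal(est$threshold, 2 * s, tolerance = 0.05)
  expect_equal(est$threshold, 2 * est$sd_pairwise)
  expect_equal(est$n_windows, n)
  expect_equal(est$fallback, 1.0)
  # guard rails: single replicate, mixed conditions
  expect_error(estimate_variability_threshold(
    dplyr::filter(prof, sample == "Ctrl_1")), ">= 2")
  prof_mixed <- make_profiles(c(vals, list(APH_1 = base)), bin_size = 1000)
  expect_error(estimate_variability_threshold(prof_mixed), "single condition")
})

test_that("variable windows require both magnitude and replicate sign consistency", {
  # window 1: clean delay (-2); window 2: big mean change but replicates
  # interleave (one APH rep above a control rep) -> not flagged;
  # window 3: consistent but sub-threshold; window 4: clean advance
  vals <- list(Ctrl_1 = c(2.0, 2.0, 0.1, -1.0),
               Ctrl_2 = c(2.2, 0.0, 0.0, -1.2),
               APH_1  = c(0.0, 0.5, -0.4, 0.3),
               APH_2  = c(0.2, -1.5, -0.5, 0.5))
  prof <- make_profiles(vals, bin_size = 100)
  w <- detect_variable_windows(prof, window = 100, threshold = 1.0)
  expect_equal(w$flagged, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(w$direction, c("delayed", NA, NA, "advanced"))
  expect_equal(w$sign_consistent, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(w$delta, c(-2, -1.5, -0.5, 1.5), tolerance = 1e-12)
  # any_pair mode flags window 3's largest pair only if it reaches the
  # threshold: max |aph - ctrl| there is |-0.5 - 0.1| = 0.6 -> still off
  w2 <- detect_variable_windows(prof, window = 100, threshold = 1.0,
                                mode = "any_pair")
  expect_equal(w2$flagged, c(TRUE, FALSE, FALSE, TRUE))
  # lowering the threshold to 0.6 flags it in any_pair but not in
  # condition_mean (|mean delta| = 0.5)
  w3 <- detect_variable_windows(prof, window = 100, threshold = 0.6,
                                mode = "any_pair")
  expect_true(w3$flagged[3])
  w4 <- detect_variable_windows(prof, window = 100, threshold = 0.6)
  expect_false(w4$flagged[3])
})

test_that("merge_contiguous matches a run-length scan oracle and never joins across gaps or directions", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 30
    w <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = 0, end = 0,
      delta = round(rnorm(n), 2),
      flagged = runif(n) < 0.6) |>
      dplyr::group_by(chrom) |>
      dplyr::mutate(start = (dplyr::row_number() - 1) * 100 +
                      cumsum(sample(c(0, 100), dplyr::n(), TRUE,
                                    prob = c(0.8, 0.2))),
                    end = start + 100) |>
      dplyr::ungroup() |>
      dplyr::mutate(direction = ifelse(!flagged, NA_character_,
                                       ifelse(delta < 0, "delayed",
                                              "advanced")),
                    mean_ctrl = round(rnorm(n), 2)) |>
      dplyr::arrange(chrom, start)
    got <- merge_contiguous(w)
    # oracle: linear scan over the sorted flagged windows
    fl <- w[w$flagged, ]
    exp_regions <- list()
    cur <- NULL
    for (i in seq_len(nrow(fl))) {
      r <- fl[i, ]
      if (!is.null(cur) && r$chrom == cur$chrom && r$start == cur$end &&
          r$direction == cur$direction) {
        cur$end <- r$end
        cur$n <- cur$n + 1
        cur$deltas <- c(cur$deltas, r$delta)
      } else {
        if (!is.null(cur)) exp_regions[[length(exp_regions) + 1]] <- cur
        cur <- list(chrom = r$chrom, start = r$start, end = r$end,
                    direction = r$direction, n = 1, deltas = r$delta)
      }
    }
    if (!is.null(cur)) exp_regions[[length(exp_regions) + 1]] <- cur
    expect_equal(nrow(got), length(exp_regions))
    expect_equal(got$start, vapply(exp_regions, `[[`, 0, "start"))
    expect_equal(got$end, vapply(exp_regions, `[[`, 0, "end"))
    expect_equal(got$direction,
                 vapply(exp_regions, `[[`, "", "direction"))
    expect_equal(got$n_windows,
                 as.integer(vapply(exp_regions, `[[`, 0, "n")))
    expect_equal(got$mean_delta,
                 vapply(exp_regions, function(r) mean(r$deltas), 0),
                 tolerance = 1e-12)
  }
  # empty input -> empty region table with the right shape
  none <- merge_contiguous(dplyr::mutate(
    tibble::tibble(chrom = "chr1", start = 0, end = 100, delta = 0,
                   mean_ctrl = 0), flagged = FALSE, direction = NA_character_))
  expect_equal(nrow(none), 0)
  expect_true(all(c("region_id", "mean_delta", "window_ids") %in% names(none)))
})

test_that("signature clustering labels planted early-delayed and late-advanced groups", {
  set.seed(41)
  n <- 60
  # windows 1..30: early in control (rt ~ 2), delayed to ~ -0.2 under APH
  # windows 31..60: late in control (rt ~ -2), advanced to ~ 0.2
  ctrl <- c(rnorm(30, 2, 0.05), rnorm(30, -2, 0.05))
  aph <- c(rnorm(30, -0.2, 0.05), rnorm(30, 0.2, 0.05))
  vals <- list(Ctrl_1 = ctrl, Ctrl_2 = ctrl + rnorm(n, 0, 0.05),
               APH_1 = aph, APH_2 = aph + rnorm(n, 0, 0.05))
  prof <- make_profiles(vals, bin_size = 100)
  w <- detect_variable_windows(prof, window = 100, threshold = 1.0)
  expect_true(all(w$flagged))
  sig <- cluster_rt_signatures(w, k = 2, seed = 1)
  expect_setequal(sig$clusters$label, c("early_delayed", "late_advanced"))
  expect_equal(sort(sig$clusters$n_windows), c(30, 30))
  expect_true(all(sig$clusters$p_adj < 0.01))
  expect_equal(nrow(tidy(sig)), 2)
  expect_equal(glance(sig)$n_windows, 60)
  expect_error(cluster_rt_signatures(w, k = 61), "exceeds")
})

test_that("band annotation counts region directions per band and composes fragile-band phases", {
  bands <- tibble::tibble(band_id = c("b1", "b2", "b3"), chrom = "chr1",
                          start = c(0, 1000, 2000), end = c(1000, 2000, 3000))
  regions <- tibble::tibble(
    region_id = c("r1", "r2", "r3"), chrom = "chr1",
    start = c(100, 900, 2100), end = c(300, 1100, 2200),
    direction = c("delayed", "advanced", "delayed"),
    n_windows = 1L, mean_delta = c(-1.5, 1.2, -1.1),
    mean_ctrl = c(1.2, 0, -1), window_ids = list("a", "b", "c"))
  ann <- annotate_bands(regions, bands, fragile_band_ids = c("b1", "b3"),
                        cuts = c(-0.5, 0.5))
  ann <- ann[order(ann$band_id), ]
  # r2 straddles b1/b2 and counts in both
  expect_equal(ann$n_delayed, c(1, 0, 1))
  expect_equal(ann$n_advanced, c(1, 1, 0))
  expect_equal(ann$category, c("both", "advanced_only", "delayed_only"))
  expect_equal(ann$fragile, c(TRUE, FALSE, TRUE))
  pc <- attr(ann, "phase_composition")
  # delayed regions in fragile bands: r1 (ctrl 1.2 -> early), r3 (-1 -> late)
  expect_equal(pc$n[pc$phase == "early"], 1L)
  expect_equal(pc$n[pc$phase == "late"], 1L)
  expect_equal(pc$n[pc$phase == "mid"], 0L)
  expect_error(annotate_bands(regions, bands, "nope"), "not in the band table")
})
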