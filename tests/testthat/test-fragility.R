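# V-shaped RT-delay detection, delay overlap and the signature call.

# noiseless planted V delta track around a gene
planted_v_track <- function(gene_start = 4e5, gene_end = 8e5, vertex = 6e5,
                            depth = -1.5, span = c(0, 1.2e6),
                            bin_size = 5e3) {
  starts <- seq(span[1], span[2] - bin_size, bin_size)
  centers <- starts + bin_size / 2
  delta <- rep(0, length(starts))
  inside <- centers >= gene_start & centers < gene_end
  shape <- ifelse(centers <= vertex,
                  1 - (vertex - centers) / (vertex - gene_start),
                  1 - (centers - vertex) / (gene_end - vertex))
  delta[inside] <- depth * pmax(shape[inside], 0)
  tibble::tibble(chrom = "chr1", start = starts, end = starts + bin_size,
                 delta = delta)
}

test_that("detect_v_shape recovers depth, vertex and CFR of a noiseless planted V", {
  gene <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                         start = 4e5, end = 8e5)
  tr <- planted_v_track(vertex = 6e5, depth = -1.5)
  v <- detect_v_shape(tr, gene, sigma_bins = 2, min_depth = 0.5,
                      cfr_fraction = 0.8)
  expect_true(v$is_v)
  expect_equal(v$depth, -1.5, tolerance = 0.05)
  expect_lt(abs(v$vertex - 6e5), 2 * 5e3)  # within 2 bins
  # CFR: bins at least 80% of the vertex depth; for a linear V of
  # half-widths 2e5 this is vertex +/- 20% of each half-width
  expect_lt(abs(v$cfr_start - (6e5 - 0.2 * 2e5)), 2 * 5e3)
  expect_lt(abs(v$cfr_end - (6e5 + 0.2 * 2e5)), 2 * 5e3)
  expect_gte(v$left_rise, 0.25)
  expect_gte(v$right_rise, 0.25)
})

test_that("asymmetric vertices and the argmin method both localize within tolerance", {
  gene <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                         start = 4e5, end = 8e5)
  tr <- planted_v_track(vertex = 4.6e5, depth = -2)  # vertex near gene start
  v_fit <- detect_v_shape(tr, gene, method = "fit")
  expect_true(v_fit$is_v)
  expect_lt(abs(v_fit$vertex - 4.6e5), 2 * 5e3)
  # the smoothed argmin drifts toward the shallow arm on asymmetric Vs
  # (the reason "fit" is the default); allow one extra bin
  v_am <- detect_v_shape(tr, gene, method = "argmin")
  expect_true(v_am$is_v)
  expect_lt(abs(v_am$vertex - 4.6e5), 3 * 5e3)
})

test_that("flat or shallow profiles are not called V-shaped", {
  gene <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                         start = 4e5, end = 8e5)
  flat <- dplyr::mutate(planted_v_track(), delta = 0.01)
  expect_false(detect_v_shape(flat, gene)$is_v)
  shallow <- planted_v_track(depth = -0.3)  # below min_depth 0.5
  expect_false(detect_v_shape(shallow, gene)$is_v)
  # a step down without a right-side rise fails the rise requirement
  step <- planted_v_track()
  step$delta <- ifelse(step$start >= 6e5, -1.5, 0)
  v <- detect_v_shape(step, gene)
  expect_false(v$is_v)
  # genes narrower than 3 bins are rejected
  tiny <- tibble::tibble(gene_id = "t", chrom = "chr1",
                         start = 4e5, end = 4.05e5)
  expect_error(detect_v_shape(planted_v_track(), tiny), "3 bins")
})

test_that("gene_rt_delay matches an all-pairs oracle on random inputs", {
  set.seed(43)
  for (rep in 1:20) {
    genes <- random_intervals(10, 1e6, 1e5)
    genes$gene_id <- paste0("g", seq_len(nrow(genes)))
    regions <- random_intervals(8, 1e6, 2e5)
    regions$region_id <- paste0("r", seq_len(nrow(regions)))
    regions$direction <- sample(c("delayed", "advanced"), nrow(regions),
                                replace = TRUE)
    regions$mean_delta <- round(ifelse(regions$direction == "delayed", -1, 1) *
                                  runif(nrow(regions), 0.5, 3), 3)
    got <- gene_rt_delay(genes, regions)
    del <- regions[regions$direction == "delayed", ]
    ov <- oracle_overlaps(genes, del)
    expect_equal(got$is_rt_delayed, rowSums(ov) > 0)
    for (i in seq_len(nrow(genes))) {
      if (any(ov[i, ])) {
        expect_equal(got$delay_magnitude[i], min(del$mean_delta[ov[i, ]]))
        expect_setequal(got$region_ids[[i]], del$region_id[ov[i, ]])
      } else {
        expect_true(is.na(got$delay_magnitude[i]))
      }
    }
  }
})

test_that("the fragility verdict is the exact conjunction of the four components", {
  # factorial cohort: all 16 combinations of the four flags
  grid <- expand.grid(is_large = c(TRUE, FALSE),
                      highly_transcribed = c(TRUE, FALSE),
                      is_rt_delayed = c(TRUE, FALSE),
                      spans_boundary = c(TRUE, FALSE))
  evidence <- tibble::as_tibble(grid)
  evidence$gene_id <- paste0("g", seq_len(nrow(evidence)))
  calls <- call_fragility_signature(evidence)
  expect_identical(calls$fragile_candidate,
                   evidence$is_large & evidence$highly_transcribed &
                     evidence$is_rt_delayed & evidence$spans_boundary)
  expect_equal(sum(calls$fragile_candidate), 1)
  funnel <- fragility_funnel(calls)
  expect_equal(funnel$cohort,
               c("large", "large_transcribed", "large_transcribed_delayed",
                 "fragile_candidate"))
  expect_equal(funnel$n, c(8, 4, 2, 1))
  # the funnel is monotone non-increasing by construction
  expect_true(all(diff(funnel$n) <= 0))
  expect_error(fragility_funnel(evidence), "call_fragility_signature")
})

test_that("evidence assembly joins on gene id and rejects incomplete components", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          start = c(0, 5e5), end = c(4e5, 9.5e5),
                          strand = "+", length = c(4e5, 4.5e5))
  sizes <- classify_sizes(genes)
  expr <- tibble::tibble(gene_id = c("a", "b"), condition = "control",
                         density = c(5, 0.1), expressed = c(TRUE, FALSE),
                         quartile = c("q4", "q1"),
                         highly_transcribed = c(TRUE, FALSE))
  arch <- classify_gene_architecture(
    genes, tibble::tibble(chrom = "chr1", start = 2e5, end = 2e5 + 1))
  delay <- gene_rt_delay(genes, tibble::tibble(
    region_id = "r1", chrom = "chr1", start = 1e5, end = 3e5,
    direction = "delayed", mean_delta = -1.4))
  ev <- assemble_gene_evidence(genes, sizes, expr, arch, delay)
  expect_equal(nrow(ev), 2)
  calls <- call_fragility_signature(ev)
  expect_identical(calls$fragile_candidate, c(TRUE, FALSE))
  expect_equal(calls$delay_magnitude[1], -1.4)
  # dropping a gene from one component is an error
  expect_error(assemble_gene_evidence(genes, sizes[1, ], expr, arch, delay),
               "missing gene id")
})

test_that("locate_cfr analyses exactly the candidates against the delta track", {
  gene <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 4e5,
                         end = 8e5, strand = "+", length = 4e5)
  tr <- planted_v_track(vertex = 6e5, depth = -1.5)
  ev <- tibble::tibble(gene_id = "g1", is_large = TRUE,
                       highly_transcribed = TRUE, is_rt_delayed = TRUE,
                       spans_boundary = TRUE)
  calls <- call_fragility_signature(ev)
  cfr <- locate_cfr(calls, tr, gene, flank_bp = 4e5)
  expect_equal(nrow(cfr), 1)
  expect_true(cfr$is_v)
  # no candidates -> typed empty result
  ev0 <- dplyr::mutate(ev, is_large = FALSE)
  cfr0 <- locate_cfr(call_fragility_signature(ev0), tr, gene)
  expect_equal(nrow(cfr0), 0)
  expect_true(all(c("gene_id", "vertex", "depth", "is_v") %in% names(cfr0)))
})
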