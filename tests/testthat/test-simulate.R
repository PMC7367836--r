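# Synthetic-data generator: planted structure and determinism.

test_that("simulated genes are non-overlapping and planted genes honor their architecture", {
  cfg <- small_sim_config(seed = 101)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$genes), cfg$n_genes)
  # no gene-gene overlap (all-pairs within chromosomes)
  by_chr <- split(sim$genes, sim$genes$chrom)
  for (gc in by_chr) {
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1) expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  truth <- sim$truth
  frag <- sim$genes[sim$genes$gene_id %in%
                      truth$gene_id[truth$planted_fragile], ]
  ctrl <- sim$genes[sim$genes$gene_id %in%
                      truth$gene_id[truth$planted_delayed_control], ]
  expect_equal(nrow(frag), cfg$n_fragile)
  expect_equal(nrow(ctrl), cfg$n_intra_tad_controls)
  # planted genes are large and highly expressed
  expect_true(all(frag$length > cfg$large_cutoff))
  expect_true(all(ctrl$length > cfg$large_cutoff))
  expect_true(all(frag$expr_level > 0))
  # re-derive architecture from the emitted boundaries: fragile genes
  # span a boundary, intra-TAD controls do not
  arch <- classify_gene_architecture(sim$genes, sim$boundaries)
  expect_true(all(arch$spans_boundary[match(frag$gene_id, arch$gene_id)]))
  expect_false(any(arch$spans_boundary[match(ctrl$gene_id, arch$gene_id)]))
  # fragile vertices sit at a boundary strictly inside the gene body
  fv <- truth$vertex[match(frag$gene_id, truth$gene_id)]
  expect_true(all(fv > frag$start & fv < frag$end))
  expect_true(all(fv %in% sim$boundaries$start))
})

test_that("zero planted genes gives an empty fragile set and generators stay deterministic", {
  cfg <- small_sim_config(seed = 5, n_fragile = 0, n_intra_tad_controls = 0)
  sim <- simulate_genome(cfg)
  expect_equal(sum(sim$truth$planted_fragile), 0)
  expect_true(all(is.na(sim$truth$vertex)))
  # identical config -> identical outputs
  sim2 <- simulate_genome(cfg)
  expect_identical(sim$genes, sim2$genes)
  expect_identical(sim$boundaries, sim2$boundaries)
  # different seed -> different placement
  sim3 <- simulate_genome(small_sim_config(seed = 6, n_fragile = 0,
                                           n_intra_tad_controls = 0))
  expect_false(identical(sim$genes$start, sim3$genes$start))
})

test_that("RT reads honor the binomial split, the RT scale and the planted delta", {
  cfg <- small_sim_config(seed = 11)
  sim <- simulate_genome(cfg)
  reads <- simulate_rt_reads(sim)
  expect_true(all(reads$counts$early + reads$counts$late ==
                    cfg$reads_per_bin))
  expect_true(all(reads$counts$early >= 0))
  lat <- reads$latent
  expect_true(all(lat$rt_control >= -3 - 1e-9 & lat$rt_control <= 3 + 1e-9))
  # latent delta is 0 outside planted genes and advanced regions;
  # at each fragile vertex it equals the configured depth
  frag <- sim$truth[sim$truth$planted_fragile, ]
  for (i in seq_len(nrow(frag))) {
    gi <- sim$genes[sim$genes$gene_id == frag$gene_id[i], ]
    vbin <- lat[lat$chrom == gi$chrom &
                  lat$start <= frag$vertex[i] & lat$end > frag$vertex[i], ]
    expect_equal(vbin$delta, cfg$delay_depth, tolerance = 0.05)
  }
  # base-2 logistic link symmetry: bins with latent RT ~ 0 have early
  # fraction ~ 0.5 on average
  ctrl_reads <- reads$counts[reads$counts$condition == "control", ]
  near0 <- abs(lat$rt_control) < 0.05
  key <- paste(lat$chrom, lat$start)
  sel <- ctrl_reads[paste(ctrl_reads$chrom, ctrl_reads$start) %in%
                      key[near0], ]
  expect_gt(nrow(sel), 50)
  expect_equal(mean(sel$early) / cfg$reads_per_bin, 0.5, tolerance = 0.05)
})

test_that("nascent counts follow gene rates and RPM densities recover the planted expression order", {
  cfg <- small_sim_config(seed = 19)
  sim <- simulate_genome(cfg)
  nas <- simulate_nascent_counts(sim)
  counts <- nas$control$counts
  expect_equal(nas$control$library_size, sum(counts$value))
  # intergenic bins are background Poisson
  hits <- unique(fragsig:::overlap_pairs(counts, sim$genes)$idx_x)
  bg <- counts$value[-hits]
  expect_equal(mean(bg), cfg$nascent_background, tolerance = 0.15)
  # quantification recovers the planted expression ordering
  q <- quantify_expression(counts, nas$control$library_size, sim$genes)
  rho <- cor(q$density, sim$genes$expr_level, method = "spearman")
  expect_gt(rho, 0.95)
  # silent genes stay near background density
  silent <- sim$genes$expr_level == 0
  expect_true(any(silent))
  expect_lt(max(q$density[silent]),
            min(q$density[sim$genes$expr_level >
                            stats::quantile(sim$genes$expr_level, 0.75)]))
})

test_that("simulated contact matrices are symmetric and their boundaries are recoverable", {
  cfg <- small_sim_config(seed = 23)
  sim <- simulate_genome(cfg)
  cm <- simulate_contact_matrix(sim, "chr1", bin_size = 2.5e4)
  expect_identical(cm$mat, t(cm$mat))
  sc <- separation_score(cm, window_bins = 10)
  called <- call_boundaries(sc, min_depth = 0.3)
  planted <- sort(sim$boundaries$start[sim$boundaries$chrom == "chr1"])
  planted_bins <- planted / 2.5e4
  # every planted boundary has a called boundary within 1 bin
  dist <- vapply(planted_bins, function(b) min(abs(called$bin + 0.5 - b)),
                 numeric(1))
  expect_true(mean(dist <= 1.5) >= 0.9)
})

test_that("simulate_dataset writes a complete self-consistent bundle, byte-identical across runs", {
  cfg <- small_sim_config(seed = 31)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- simulate_dataset(cfg, dir1)
  m2 <- simulate_dataset(cfg, dir2)
  files <- c("genome.chrom.sizes", "genes.bed", "tad_boundaries.bed",
             "bands.tsv", "ground_truth.tsv", "nascent_control.bedGraph")
  for (f in files) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readBin(file.path(dir1, f), "raw",
                             file.size(file.path(dir1, f))),
                     readBin(file.path(dir2, f), "raw",
                             file.size(file.path(dir2, f))))
  }
  expect_equal(nrow(m1$samples), 2 * cfg$n_replicates)
  expect_true(all(file.exists(m1$samples$early_path)))
  # emitted genes re-load to the in-memory catalog
  genes <- read_gene_annotation(m1$genes, "bed")
  expect_equal(genes$gene_id, m1$sim$genes$gene_id)
  expect_equal(genes$start, m1$sim$genes$start)
  # fragile bands really contain a planted fragile gene
  bands <- readr::read_tsv(m1$bands, col_types = "ccdd", progress = FALSE)
  frag_genes <- m1$sim$genes[m1$sim$genes$gene_id %in%
                               m1$sim$truth$gene_id[m1$sim$truth$planted_fragile], ]
  for (b in m1$fragile_band_ids) {
    brow <- bands[bands$band_id == b, ]
    expect_gt(nrow(fragsig:::overlap_pairs(brow, frag_genes)), 0)
  }
})
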