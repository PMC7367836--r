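# Synthetic multi-omic data with planted ground truth.
#
# The generator emulates the structure the pipeline was designed for:
# smooth RT landscapes on the [-3, 3] log2(early/late) scale, a gene
# catalog with a heavy tail of > 300 kb genes, zero-inflated expression,
# TAD segmentation every ~0.4-1.2 Mb, planted V-shaped APH delays at
# expressed large boundary-spanning genes (plus intra-TAD delayed
# controls for the negative arm), and binomial early/late read sampling
# conditioned on RT through a base-2 logistic link, so the latent RT
# field and the measured log2(E/L) share a scale.

#' Simulation configuration
#'
#' Every generator is a deterministic function of this configuration
#' (the seed covers all randomness). Defaults give a 4 x 50 Mb genome
#' with 500 genes, ~100 TADs per genome, 12 planted fragile genes and
#' 12 intra-TAD delayed controls with V depth -1.5 RT units, 4 + 4
#' replicates with 0.2 RT-unit replicate noise and 200 reads per 5 kb
#' bin.
#'
#' @param seed mandatory RNG seed.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes total gene count.
#' @param gene_meanlog,gene_sdlog log-normal body of gene lengths (bp).
#' @param large_fraction fraction of genes drawn from the Pareto tail
#'   above `large_cutoff`.
#' @param pareto_alpha tail index of the large-gene length distribution.
#' @param large_cutoff bp cutoff of the large class (300 kb).
#' @param zero_inflation probability a gene is silent.
#' @param expr_meanlog,expr_sdlog log-normal expression scale (per-kb
#'   Poisson rate units).
#' @param tad_spacing_min,tad_spacing_max TAD boundary spacing range bp.
#' @param n_fragile planted fragile (boundary-spanning) genes.
#' @param n_intra_tad_controls planted intra-TAD delayed controls.
#' @param delay_depth V vertex depth in RT units (negative = delayed).
#' @param n_advanced,advanced_magnitude,advanced_width planted advanced
#'   regions.
#' @param n_replicates replicates per condition.
#' @param replicate_sd per-bin replicate noise SD on latent RT.
#' @param reads_per_bin early + late reads per RT bin.
#' @param rt_bin_size,nascent_bin_size track resolutions (bp).
#' @param nascent_background intergenic Poisson rate per nascent bin.
#' @param planted_expr_quantile quantile of the positive expression
#'   scale at which planted genes are expressed (keeps them in q3/q4).
#' @param rt_smooth_bins smoothing SD (in bins) of the latent RT field.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              n_chromosomes = 4,
                              chrom_length = 5e7,
                              n_genes = 500,
                              gene_meanlog = log(4e4),
                              gene_sdlog = 0.9,
                              large_fraction = 0.08,
                              pareto_alpha = 2.5,
                              large_cutoff = 3e5,
                              zero_inflation = 0.2,
                              expr_meanlog = log(2),
                              expr_sdlog = 1.2,
                              tad_spacing_min = 4e5,
                              tad_spacing_max = 1.2e6,
                              n_fragile = 12,
                              n_intra_tad_controls = 12,
                              delay_depth = -1.5,
                              n_advanced = 10,
                              advanced_magnitude = 1.2,
                              advanced_width = 3e5,
                              n_replicates = 4,
                              replicate_sd = 0.2,
                              reads_per_bin = 200,
                              rt_bin_size = 5e3,
                              nascent_bin_size = 1e3,
                              nascent_background = 0.05,
                              planted_expr_quantile = 0.9,
                              rt_smooth_bins = 60) {
  if (missing(seed)) abort("`seed` is mandatory.")
  cfg <- as.list(environment())
  counts <- c("n_chromosomes", "n_genes", "n_fragile",
              "n_intra_tad_controls", "n_advanced", "n_replicates",
              "reads_per_bin")
  for (nm in counts) {
    if (cfg[[nm]] < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  if (cfg$delay_depth > 0) abort("`delay_depth` must be <= 0 (a delay).")
  structure(cfg, class = "simulation_config")
}

# Pareto lengths above a floor: floor * (1 - u)^(-1/alpha), capped so a
# planted gene always fits inside one chromosome with flanks.
rpareto <- function(n, floor, alpha, cap) {
  pmin(floor * (1 - runif(n))^(-1 / alpha), cap)
}

#' Simulate genome, genes, TAD boundaries and ground truth
#'
#' Genes are placed uniformly without overlap. Planted fragile genes
#' are large (> 300 kb), assigned a high expression level, and
#' positioned so a TAD boundary falls strictly inside the gene body;
#' intra-TAD delayed controls share size and expression but are placed
#' fully inside a TAD (no boundary in the body), exercising the
#' negative arm of the signature.
#'
#' @param config a [simulation_config()].
#' @return List with `genome` (genome table), `genes` (gene table plus
#'   `expr_level`), `boundaries` (boundary tibble), `truth` (per-gene
#'   `planted_fragile`, `planted_delayed_control`, `vertex` bp),
#'   `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genome <- genome_table(paste0("chr", seq_len(config$n_chromosomes)),
                         rep(config$chrom_length, config$n_chromosomes))
  # TAD boundaries: cumulative uniform spacing per chromosome
  boundaries <- purrr::map(genome$chrom, function(ch) {
    pos <- cumsum(runif(ceiling(config$chrom_length / config$tad_spacing_min),
                        config$tad_spacing_min, config$tad_spacing_max))
    pos <- pos[pos < config$chrom_length - config$tad_spacing_min]
    tibble(chrom = ch, start = round_half_up(pos),
           end = round_half_up(pos) + 1, score = NA_real_)
  }) %>% bind_rows()

  n_planted <- config$n_fragile + config$n_intra_tad_controls
  if (n_planted > config$n_genes) abort("More planted genes than genes.")
  n_other <- config$n_genes - n_planted
  n_large_other <- stats::rbinom(1, n_other, config$large_fraction)
  cap <- config$chrom_length / 10
  lengths_other <- c(
    rpareto(n_large_other, config$large_cutoff, config$pareto_alpha, cap),
    pmin(rlnorm(n_other - n_large_other, config$gene_meanlog,
                config$gene_sdlog), config$large_cutoff - 1))
  lengths_other <- round_half_up(pmax(lengths_other, 1000))
  lengths_planted <- round_half_up(runif(n_planted, 3.5e5, 6e5))

  # place planted genes around/inside TADs first, then the rest
  occupied <- tibble(chrom = character(), start = numeric(), end = numeric())
  place_planted <- function(len, need_boundary) {
    for (i in seq_len(5000)) {
      if (need_boundary) {
        b <- boundaries[sample(nrow(boundaries), 1), ]
        # boundary midpoint lands in the central 60% of the gene
        off <- runif(1, 0.2, 0.8)
        start <- round_half_up(b$start - off * len)
        ch <- b$chrom
      } else {
        # fit between two consecutive boundaries with margin
        ch <- sample(genome$chrom, 1)
        bs <- c(0, boundaries$start[boundaries$chrom == ch],
                config$chrom_length)
        gaps <- which(diff(bs) > len + 2e4)
        if (length(gaps) == 0) next
        g <- sample(rep(gaps, 2), 1)
        start <- round_half_up(runif(1, bs[g] + 1e4, bs[g + 1] - len - 1e4))
      }
      end <- start + len
      if (start < 1e4 || end > config$chrom_length - 1e4) next
      cur <- tibble(chrom = ch, start = start, end = end)
      if (nrow(overlap_pairs(cur, occupied)) == 0) {
        occupied <<- bind_rows(occupied, cur)
        return(cur)
      }
    }
    abort("Genome too small to place planted genes.")
  }
  planted <- purrr::map2(
    lengths_planted,
    rep(c(TRUE, FALSE), c(config$n_fragile, config$n_intra_tad_controls)),
    place_planted) %>% bind_rows()

  place_other <- function(len) {
    for (i in seq_len(5000)) {
      ch <- sample(genome$chrom, 1)
      start <- floor(runif(1) * (config$chrom_length - len))
      cur <- tibble(chrom = ch, start = start, end = start + len)
      if (nrow(overlap_pairs(cur, occupied)) == 0) {
        occupied <<- bind_rows(occupied, cur)
        return(cur)
      }
    }
    abort("Genome too small to place genes without overlap.")
  }
  others <- purrr::map(lengths_other, place_other) %>% bind_rows()

  genes <- bind_rows(planted, others) %>%
    mutate(gene_id = sprintf("gene_%04d", row_number()),
           strand = sample(c("+", "-"), n(), replace = TRUE),
           length = .data$end - .data$start)
  n_genes <- nrow(genes)
  # expression: planted genes high; others zero-inflated log-normal
  lv <- rlnorm(n_genes, config$expr_meanlog, config$expr_sdlog)
  lv[runif(n_genes) < config$zero_inflation] <- 0
  planted_level <- stats::qlnorm(config$planted_expr_quantile,
                                 config$expr_meanlog, config$expr_sdlog)
  lv[seq_len(n_planted)] <- planted_level * runif(n_planted, 1, 2)
  genes$expr_level <- lv

  is_fragile <- seq_len(n_genes) <= config$n_fragile
  is_control <- seq_len(n_genes) > config$n_fragile &
    seq_len(n_genes) <= n_planted
  # delay vertex: the contained boundary for fragile genes (the most
  # delayed point sits at the TAD boundary), gene midpoint for controls
  vertex <- rep(NA_real_, n_genes)
  for (i in which(is_fragile)) {
    b <- boundaries %>%
      filter(.data$chrom == genes$chrom[i], .data$start > genes$start[i],
             .data$start < genes$end[i])
    vertex[i] <- b$start[1]
  }
  vertex[is_control] <- floor((genes$start[is_control] +
                                 genes$end[is_control]) / 2)
  truth <- tibble(gene_id = genes$gene_id, planted_fragile = is_fragile,
                  planted_delayed_control = is_control, vertex = vertex,
                  expr_level = lv)
  genes <- genes %>%
    select("gene_id", "chrom", "start", "end", "strand", "length",
           "expr_level") %>%
    arrange(.data$chrom, .data$start)
  list(genome = genome, genes = genes, boundaries = boundaries,
       truth = truth, config = config)
}

# planted APH-minus-control delta field on the bin frame
planted_delta <- function(sim, frame) {
  config <- sim$config
  delta <- rep(0, nrow(frame))
  centers <- (frame$start + frame$end) / 2
  planted <- sim$truth %>% filter(!is.na(.data$vertex))
  gl <- sim$genes[match(planted$gene_id, sim$genes$gene_id), ]
  for (i in seq_len(nrow(planted))) {
    v <- planted$vertex[i]
    idx <- which(frame$chrom == gl$chrom[i] & centers >= gl$start[i] &
                   centers < gl$end[i])
    if (length(idx) == 0) next
    x <- centers[idx]
    hl <- pmax(v - gl$start[i], 1)
    hr <- pmax(gl$end[i] - v, 1)
    shape <- ifelse(x <= v, 1 - (v - x) / hl, 1 - (x - v) / hr)
    delta[idx] <- delta[idx] + config$delay_depth * pmax(shape, 0)
  }
  delta
}

#' Simulate early/late Repli-seq counts per replicate and condition
#'
#' The latent control RT per chromosome is a Gaussian-smoothed random
#' field rescaled to [-3, 3]; the APH RT adds the planted V-shaped
#' deltas (at fragile genes and intra-TAD controls) and advanced bumps.
#' Each replicate adds N(0, replicate_sd) noise on the latent RT, the
#' per-bin early-read fraction is the base-2 logistic
#' p = 1 / (1 + 2^-RT) (so RT = 0 gives p = 0.5 and the measured
#' log2(E/L) is centred on the latent RT), and reads are
#' Binomial(reads_per_bin, p) split into early/late.
#'
#' @param sim output of [simulate_genome()].
#' @return List: `counts` — tibble `chrom`, `start`, `end`, `sample`,
#'   `condition`, `replicate`, `early`, `late`; `latent` — tibble with
#'   the noiseless control/APH RT and delta per bin; `advanced_regions`
#'   — the planted advanced intervals.
#' @export
simulate_rt_reads <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 1L)
  frame <- tile_genome(sim$genome, config$rt_bin_size)
  # smooth latent control landscape
  ctrl <- unlist(purrr::map(sim$genome$chrom, function(ch) {
    n <- sum(frame$chrom == ch)
    z <- gauss_smooth(rnorm(n), config$rt_smooth_bins)
    -3 + 6 * (z - min(z)) / (max(z) - min(z))
  }), use.names = FALSE)
  delta <- planted_delta(sim, frame)
  # advanced bumps: plateaus clear of all genes
  adv <- tibble(chrom = character(), start = numeric(), end = numeric())
  if (config$n_advanced > 0) {
    for (i in seq_len(config$n_advanced)) {
      for (try in seq_len(1000)) {
        ch <- sample(sim$genome$chrom, 1)
        start <- floor(runif(1) * (config$chrom_length - config$advanced_width))
        cur <- tibble(chrom = ch, start = start,
                      end = start + config$advanced_width)
        if (nrow(overlap_pairs(cur, sim$genes)) == 0 &&
            nrow(overlap_pairs(cur, adv)) == 0) {
          adv <- bind_rows(adv, cur)
          break
        }
      }
    }
    hits <- overlap_pairs(frame, adv)
    delta[unique(hits$idx_x)] <- delta[unique(hits$idx_x)] +
      config$advanced_magnitude
  }
  aph <- ctrl + delta
  counts <- purrr::map(c("control", "APH"), function(cond) {
    latent <- if (cond == "control") ctrl else aph
    purrr::map(seq_len(config$n_replicates), function(r) {
      rt <- latent + rnorm(length(latent), 0, config$replicate_sd)
      p <- 1 / (1 + 2^(-rt))
      early <- rbinom(length(p), config$reads_per_bin, p)
      tibble(chrom = frame$chrom, start = frame$start, end = frame$end,
             sample = sprintf("%s_%d", ifelse(cond == "APH", "APH", "Ctrl"), r),
             condition = cond, replicate = r,
             early = early, late = config$reads_per_bin - early)
    }) %>% bind_rows()
  }) %>% bind_rows()
  latent_tbl <- frame %>%
    select("chrom", "start", "end") %>%
    mutate(rt_control = ctrl, rt_aph = aph, delta = delta)
  list(counts = counts, latent = latent_tbl, advanced_regions = adv)
}

#' Simulate nascent-RNA (Bru-seq style) counts
#'
#' Per 1 kb bin, counts are Poisson with rate = intergenic background
#' plus the gene's expression level inside gene bodies (gene-body
#' signal, as for nascent RNA). Library size is the total count.
#' Expression is simulated identically in both conditions (mild APH
#' stress leaves transcription essentially unchanged).
#'
#' @param sim output of [simulate_genome()].
#' @return List per condition: `counts` (tibble `chrom`, `start`,
#'   `end`, `value`) and `library_size`.
#' @export
simulate_nascent_counts <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 2L)
  frame <- tile_genome(sim$genome, config$nascent_bin_size)
  rate <- rep(config$nascent_background, nrow(frame))
  hits <- overlap_pairs(frame, sim$genes)
  frac <- (pmin(frame$end[hits$idx_x], sim$genes$end[hits$idx_y]) -
             pmax(frame$start[hits$idx_x], sim$genes$start[hits$idx_y])) /
    (frame$end[hits$idx_x] - frame$start[hits$idx_x])
  lvl <- tibble(i = hits$idx_x,
                add = frac * sim$genes$expr_level[hits$idx_y]) %>%
    group_by(.data$i) %>% summarise(add = sum(.data$add), .groups = "drop")
  rate[lvl$i] <- rate[lvl$i] + lvl$add
  out <- purrr::map(c("control", "APH"), function(cond) {
    value <- rpois(length(rate), rate)
    list(counts = tibble(chrom = frame$chrom, start = frame$start,
                         end = frame$end, value = value),
         library_size = sum(value))
  })
  names(out) <- c("control", "APH")
  out
}

#' Simulate a Hi-C contact matrix with planted TAD structure
#'
#' Expected contacts decay with distance as (1 + |i - j|)^-1, scaled
#' down by `contrast` between bins in different TADs; observed counts
#' are Poisson, symmetrized by construction.
#'
#' @param sim output of [simulate_genome()] (uses its boundaries).
#' @param chrom chromosome to simulate.
#' @param bin_size matrix resolution (default 25 kb).
#' @param scale expected contact at distance 0 within a TAD.
#' @param contrast within/between TAD contact ratio (default 10).
#' @return A `contact_matrix`.
#' @export
simulate_contact_matrix <- function(sim, chrom, bin_size = 2.5e4,
                                    scale = 100, contrast = 10) {
  config <- sim$config
  set.seed(config$seed + 3L)
  len <- sim$genome$length[sim$genome$chrom == chrom]
  n <- floor(len / bin_size)
  b <- sort(sim$boundaries$start[sim$boundaries$chrom == chrom])
  tad_of <- findInterval((seq_len(n) - 0.5) * bin_size, b)
  i <- row(matrix(0, n, n)); j <- col(matrix(0, n, n))
  mu <- scale * (1 + abs(i - j))^(-1)
  mu[tad_of[i] != tad_of[j]] <- mu[tad_of[i] != tad_of[j]] / contrast
  upper <- upper.tri(mu, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[upper] <- rpois(sum(upper), mu[upper])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(counts, chrom, bin_size)
}

#' Write a complete simulated dataset to disk
#'
#' Emits exactly the formats the pipeline consumes: chrom.sizes, gene
#' BED6, TAD-boundary BED, per-replicate early/late bedGraphs, per-
#' condition nascent-count bedGraphs with library sizes, a cytogenetic
#' band table (10 Mb tiles; bands containing a planted fragile gene are
#' the fragile set), and a ground-truth TSV. Deterministic in
#' (config, seed): identical calls produce byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created).
#' @return A manifest list of file paths, the samples table, library
#'   sizes, fragile band ids, and the in-memory `sim`, `reads`,
#'   `nascent` objects.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  reads <- simulate_rt_reads(sim)
  nascent <- simulate_nascent_counts(sim)
  p <- function(...) file.path(dir, paste0(...))
  readr::write_tsv(sim$genome, p("genome.chrom.sizes"), col_names = FALSE,
                   progress = FALSE)
  write_interval_table(
    sim$genes %>% mutate(name = .data$gene_id, score = 0),
    p("genes.bed"), format = "bed")
  write_interval_table(sim$boundaries, p("tad_boundaries.bed"),
                       format = "bed")
  samples <- reads$counts %>%
    distinct(.data$sample, .data$condition, .data$replicate) %>%
    mutate(early_path = p(.data$sample, "_early.bedGraph"),
           late_path = p(.data$sample, "_late.bedGraph"))
  for (i in seq_len(nrow(samples))) {
    sub <- reads$counts %>% filter(.data$sample == samples$sample[i])
    write_bedgraph(sub %>% rename(value = "early"), samples$early_path[i])
    write_bedgraph(sub %>% rename(value = "late"), samples$late_path[i])
  }
  nascent_paths <- c(control = p("nascent_control.bedGraph"),
                     APH = p("nascent_APH.bedGraph"))
  write_bedgraph(nascent$control$counts, nascent_paths["control"])
  write_bedgraph(nascent$APH$counts, nascent_paths["APH"])
  # 10 Mb band tiles; fragile = bands containing a planted fragile gene
  bands <- tile_genome(sim$genome, 1e7) %>%
    mutate(band_id = sprintf("%s_band%02d", .data$chrom, .data$bin + 1)) %>%
    select("band_id", "chrom", "start", "end")
  frag_genes <- sim$genes %>%
    filter(.data$gene_id %in%
             sim$truth$gene_id[sim$truth$planted_fragile])
  fragile_band_ids <- unique(
    bands$band_id[overlap_pairs(bands, frag_genes)$idx_x])
  readr::write_tsv(bands, p("bands.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth %>% select(-dplyr::any_of("expr_level")),
                   p("ground_truth.tsv"), progress = FALSE)
  list(dir = dir,
       chrom_sizes = p("genome.chrom.sizes"),
       genes = p("genes.bed"),
       boundaries = p("tad_boundaries.bed"),
       bands = p("bands.tsv"),
       fragile_band_ids = fragile_band_ids,
       samples = samples,
       nascent = nascent_paths,
       library_sizes = c(control = nascent$control$library_size,
                         APH = nascent$APH$library_size),
       truth = p("ground_truth.tsv"),
       sim = sim, reads = reads, nascent_data = nascent)
}
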