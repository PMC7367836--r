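# End-to-end driver: RT profiles -> variability -> signatures ->
# transcription -> architecture -> fragility calls and report files.

#' Pipeline configuration
#'
#' Names every input and effective parameter of [run_pipeline()].
#'
#' @param chrom_sizes chrom-sizes file path.
#' @param samples tibble with `sample`, `condition` ("control"/"APH"),
#'   `replicate`, `early_path`, `late_path` (bedGraph read counts).
#' @param genes gene annotation path.
#' @param genes_format `"bed"` or `"gtf-minimal"`.
#' @param nascent named character vector of nascent-count bedGraph
#'   paths, at least `control`.
#' @param library_sizes named numeric vector matching `nascent`.
#' @param boundaries TAD-boundary BED path (pre-called boundaries), or
#'   `NULL` to skip architecture (all genes then intra-TAD).
#' @param bands optional band table TSV (`band_id`, `chrom`, `start`,
#'   `end`).
#' @param fragile_band_ids optional fragile band ids for the band
#'   summary.
#' @param ctcf optional CTCF peak BED path.
#' @param out_dir report directory.
#' @param rt_bin_size,nascent_bin_size track resolutions (bp).
#' @param pseudocount,min_coverage see [compute_rt_profile()].
#' @param window,threshold,mode see [detect_variable_windows()];
#'   `threshold = NULL` calibrates it from the control replicates via
#'   [estimate_variability_threshold()].
#' @param k_signatures k for [cluster_rt_signatures()]; clustering is
#'   skipped when fewer flagged windows exist.
#' @param silence_floor,large_cutoff,late_cutoff classification cutoffs.
#' @param min_depth,cfr_fraction,flank_bp,sigma_bins V-shape/CFR
#'   parameters ([detect_v_shape()]).
#' @param require_v require a called V-shape for the final verdict
#'   (default `FALSE`: the delayed-region overlap gates the call, the
#'   V-shape refines the CFR).
#' @param seed RNG seed (k-means restarts, enrichment shuffles).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(chrom_sizes, samples, genes, nascent,
                            library_sizes, boundaries = NULL,
                            genes_format = "bed", bands = NULL,
                            fragile_band_ids = character(), ctcf = NULL,
                            out_dir = tempfile("fragsig_run"),
                            rt_bin_size = 5e3, nascent_bin_size = 1e3,
                            pseudocount = 1, min_coverage = 10,
                            window = 1e5, threshold = 1.0,
                            mode = "condition_mean", k_signatures = 5,
                            silence_floor = 0.5, large_cutoff = 3e5,
                            late_cutoff = 2.5e5, min_depth = 0.5,
                            cfr_fraction = 0.8, flank_bp = 5e5,
                            sigma_bins = 2, require_v = FALSE, seed = 1) {
  cfg <- as.list(environment())
  assert_columns(samples, c("sample", "condition", "replicate",
                            "early_path", "late_path"), "samples")
  if (!"control" %in% names(cfg$nascent)) {
    abort("`nascent` must name at least a 'control' counts file.")
  }
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full fragility-signature pipeline
#'
#' Executes Repli-seq profiling, RT-variability detection, signature
#' clustering, nascent-transcription classification, TAD architecture
#' classification and the fragility call, then writes the report
#' bundle: `candidates.bed` (name = gene id, score = |delay| x 100
#' clamped to 0..1000), `funnel.tsv`, `gene_evidence.tsv`,
#' `signatures.tsv`, `regions.tsv`, `band_summary.tsv` (when bands are
#' supplied) and `run_log.tsv` with every effective parameter and the
#' seed. Reruns with an identical configuration produce byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return (Invisibly) a list with all intermediate results: profiles,
#'   windows, regions, signatures, expression, architecture, calls,
#'   cfr, paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genome <- run_stage("io", read_chrom_sizes(config$chrom_sizes))
  genes <- run_stage("io", read_gene_annotation(config$genes,
                                                config$genes_format))

  profiles <- run_stage("repliseq", {
    purrr::map(seq_len(nrow(config$samples)), function(i) {
      s <- config$samples[i, ]
      compute_rt_profile(
        read_bedgraph(s$early_path, genome, config$rt_bin_size),
        read_bedgraph(s$late_path, genome, config$rt_bin_size),
        pseudocount = config$pseudocount,
        min_coverage = config$min_coverage,
        sample_id = s$sample, condition = s$condition,
        replicate = s$replicate)
    }) %>% bind_rows() %>% quantile_normalize()
  })

  threshold <- config$threshold
  if (is.null(threshold)) {
    threshold <- run_stage("rt_variability", {
      estimate_variability_threshold(
        profiles %>% filter(.data$condition == "control"),
        window = config$window)$threshold
    })
  }

  windows <- run_stage("rt_variability", {
    detect_variable_windows(profiles, window = config$window,
                            threshold = threshold, mode = config$mode)
  })
  regions <- run_stage("rt_variability", merge_contiguous(windows))
  signatures <- NULL
  if (sum(windows$flagged) >= config$k_signatures) {
    signatures <- run_stage("rt_variability", {
      cluster_rt_signatures(windows, k = config$k_signatures,
                            seed = config$seed)
    })
  }

  expression <- run_stage("transcription", {
    quantify_expression(
      read_bedgraph(config$nascent[["control"]], genome,
                    config$nascent_bin_size),
      config$library_sizes[["control"]], genes,
      silence_floor = config$silence_floor) %>%
      classify_quartiles()
  })
  sizes <- run_stage("transcription", {
    classify_sizes(genes, large_cutoff = config$large_cutoff,
                   late_cutoff = config$late_cutoff)
  })

  boundaries <- if (!is.null(config$boundaries)) {
    run_stage("tad_architecture", read_boundaries(config$boundaries))
  } else {
    tibble(chrom = character(), start = numeric(), end = numeric(),
           score = numeric())
  }
  architecture <- run_stage("tad_architecture",
                            classify_gene_architecture(genes, boundaries))

  enrichment <- NULL
  if (!is.null(config$ctcf) && nrow(boundaries) > 0) {
    enrichment <- run_stage("tad_architecture", {
      peaks <- read_boundaries(config$ctcf)
      ctcf_boundary_enrichment(peaks, boundaries, genome,
                               seed = config$seed)
    })
  }

  delta <- run_stage("fragility", rt_delta(profiles))
  delay <- run_stage("fragility", gene_rt_delay(genes, regions))
  evidence <- run_stage("fragility", {
    assemble_gene_evidence(genes, sizes, expression, architecture, delay)
  })
  calls <- run_stage("fragility", call_fragility_signature(evidence))
  cfr <- run_stage("fragility", {
    locate_cfr(calls, delta, genes, flank_bp = config$flank_bp,
               sigma_bins = config$sigma_bins, min_depth = config$min_depth,
               cfr_fraction = config$cfr_fraction)
  })
  if (config$require_v) {
    ok <- calls$gene_id %in% cfr$gene_id[cfr$is_v]
    calls$fragile_candidate <- calls$fragile_candidate & ok
  }

  band_summary <- NULL
  if (!is.null(config$bands)) {
    band_summary <- run_stage("rt_variability", {
      bands <- readr::read_tsv(config$bands, col_types = "ccdd",
                               progress = FALSE)
      annotate_bands(regions, bands, config$fragile_band_ids)
    })
  }

  # --- report bundle ---
  p <- function(f) file.path(config$out_dir, f)
  cand <- calls %>%
    filter(.data$fragile_candidate) %>%
    left_join(cfr, by = "gene_id") %>%
    mutate(name = .data$gene_id,
           score = abs(dplyr::coalesce(.data$delay_magnitude, 0)) * 100)
  write_interval_table(
    cand %>% select("chrom", "start", "end", "name", "score", "strand"),
    p("candidates.bed"), format = "bed")
  readr::write_tsv(fragility_funnel(calls), p("funnel.tsv"),
                   progress = FALSE)
  write_interval_table(
    as_tibble(calls) %>%
      select(-dplyr::any_of(c("boundary_ids", "region_ids"))) %>%
      left_join(select(cfr, "gene_id", "vertex", "depth", "is_v",
                       "cfr_start", "cfr_end"), by = "gene_id"),
    p("gene_evidence.tsv"), format = "tsv")
  write_interval_table(regions %>% select(-"window_ids"),
                       p("regions.tsv"), format = "tsv")
  if (!is.null(signatures)) {
    readr::write_tsv(signatures$clusters, p("signatures.tsv"),
                     progress = FALSE)
  }
  if (!is.null(band_summary)) {
    readr::write_tsv(as_tibble(band_summary), p("band_summary.tsv"),
                     progress = FALSE)
  }
  log_params <- config[!vapply(config, is.function, logical(1))]
  log_params$samples <- paste(config$samples$sample, collapse = ",")
  log_params$threshold <- threshold
  log_tbl <- tibble(parameter = names(log_params),
                    value = vapply(log_params, function(v)
                      paste(format(unlist(v), trim = TRUE), collapse = ","),
                      character(1)))
  readr::write_tsv(log_tbl, p("run_log.tsv"), progress = FALSE)

  invisible(list(genome = genome, genes = genes, profiles = profiles,
                 threshold = threshold, windows = windows,
                 regions = regions, signatures = signatures,
                 expression = expression, sizes = sizes,
                 boundaries = boundaries, architecture = architecture,
                 enrichment = enrichment, delta = delta, calls = calls,
                 cfr = cfr, band_summary = band_summary,
                 out_dir = config$out_dir))
}
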