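#' Package configuration with all analysis thresholds
#'
#' Returns the named list of every tunable threshold and simulator
#' parameter, at its default. Defaults follow the published analysis
#' conventions of the assay: a joint Levenshtein budget of 6 for barcode
#' clustering, the 4-bp cluster pairing offset of the piggyBac target-site
#' duplication, cluster support of at least 6 reads or 3 distinct aligned
#' lengths, parental amplicon support above 50 reads and 30 UMIs,
#' rearrangement calls above 1 UMI, the 0.2 chimeric-UMI read-share
#' cutoff, Hamming-1 UMI collapse, and the clonotype reconstruction and
#' assignment thresholds (>= 3 UMI per pair per cell, >= 20 total UMIs,
#' rank-ratio inflection 1.5, maximum detection fraction > 0.5, > 6 pairs,
#' Jaccard merge levels 0.95/0.1/0.05, recall > 0.1, precision > 0.75,
#' second recall <= 0.1, >= 2 UMI for assignment and single-cell calls,
#' QC at > 1000 transcriptome UMIs, 1-12% mitochondrial reads, doublet
#' score < 0.4, 100k reads per clone well).
#'
#' @param ... named overrides of any default; unknown names are an error.
#' @return classed list (`shuffle_config`).
#' @export
shuffleConfig <- function(...) {
  defaults <- list(
    ## insertion mapping
    levenshtein_budget = 6L,
    cluster_pair_offset = 4L,
    min_cluster_reads = 6L,
    min_unique_lengths = 3L,
    parental_min_reads = 50,
    parental_min_umis = 30,
    ## bulk rearrangement calling
    rearrangement_min_umi = 2L,
    cpm_scale = 1e6,
    well_min_reads = 1e5,
    ## single-cell matrix
    chimera_min_share = 0.2,
    umi_hamming = 1L,
    ## clonotype reconstruction
    clonotype_min_umi_per_pair = 3L,
    min_cell_total_umi = 20L,
    min_pair_total_umi = 20L,
    knn_neighbors = 10L,
    cluster_resolution = 1,
    rank_ratio_cut = 1.5,
    min_max_detection_fraction = 0.5,
    min_clonotype_pairs = 7L,
    jaccard_merge = 0.95,
    jaccard_connect = 0.1,
    jaccard_bulk = 0.05,
    sc_norm_scale = 1e4,
    ## cell assignment
    assign_min_umi = 2L,
    assign_min_recall = 0.1,
    assign_min_precision = 0.75,
    doublet_second_recall = 0.1,
    ## cell QC
    qc_min_umi = 1000,
    qc_mito_range = c(1, 12),
    qc_doublet_max = 0.4,
    ## simulator
    sim_chrom_lengths = c(chr1 = 5e5, chr2 = 5e5),
    sim_variant_spacing = 150,
    sim_n_clones = 20L,
    sim_insertions_per_clone = 20L,
    sim_cis_rate = 2,
    sim_trans_rate = 0.2,
    sim_cis_decay_lambda = 1e5,
    sim_ivt_depth_per_side = 10L,
    sim_ivt_read_len = 120L,
    sim_ivt_err_rate = 0.001,
    sim_amplicon_molecules = 40L,
    sim_amplicon_reads_per_umi = 2L,
    sim_chimera_rate = 0,
    sim_n_cells = 1000L,
    sim_capture_rate = 0.7,
    sim_umi_depth = 4,
    sim_ambient_rate = 0.02,
    sim_doublet_rate = 0.03,
    seed = 1L)
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides)))
    overrides <- overrides[[1L]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, overrides)
  validateConfig(cfg)
  class(cfg) <- c("shuffle_config", "list")
  cfg
}

validateConfig <- function(cfg) {
  if (cfg$sim_cis_decay_lambda <= 0)
    stop("sim_cis_decay_lambda must be > 0")
  for (p in c("sim_capture_rate", "sim_ambient_rate", "sim_doublet_rate",
              "sim_chimera_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must be in [0, 1]")
  }
  if (cfg$levenshtein_budget < 0) stop("levenshtein_budget must be >= 0")
  if (length(cfg$qc_mito_range) != 2L ||
      cfg$qc_mito_range[1L] > cfg$qc_mito_range[2L])
    stop("qc_mito_range must be an ordered pair")
  invisible(cfg)
}

#' Load configuration from a YAML or JSON file
#'
#' Values in the file override package defaults; keys not known to
#' [shuffleConfig()] raise an error, as do out-of-range values. An empty
#' file yields all defaults.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a `shuffle_config` list.
#' @export
loadConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if ("sim_chrom_lengths" %in% names(raw))
    raw$sim_chrom_lengths <- unlist(raw$sim_chrom_lengths)
  do.call(shuffleConfig, raw)
}

#' @rdname loadConfig
#' @param config a `shuffle_config` list.
#' @export
saveConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$sim_chrom_lengths <- as.list(cfg$sim_chrom_lengths)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
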