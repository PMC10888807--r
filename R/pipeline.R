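#' Run the full synthetic pipeline end to end
#'
#' Orchestrates simulate, map-insertions, call-svs, validate-ivt and
#' sc-genotype on one configuration, leaving intermediate artifacts on
#' disk and returning (and writing) a run manifest with the configuration
#' hash, seeds and per-stage record counts. With the same configuration
#' and seed, all written tables are identical across runs.
#'
#' @param config a [shuffleConfig()] list.
#' @param outDir output directory.
#' @param stages subset of
#'   `c("simulate", "map", "call", "validate", "sc")`; stages depend on
#'   all earlier ones being in the list or already on disk.
#' @param force overwrite an existing manifest.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = shuffleConfig(), outDir,
                        stages = c("simulate", "map", "call", "validate",
                                   "sc"),
                        force = FALSE) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  manifestPath <- file.path(outDir, "manifest.json")
  if (file.exists(manifestPath) && !force)
    stop("manifest exists; use force = TRUE to overwrite")
  seed <- config$seed
  counts <- list()

  sim <- NULL
  if ("simulate" %in% stages) {
    sim <- simulateShuffleExperiment(
      chromLengths = config$sim_chrom_lengths,
      nClones = config$sim_n_clones,
      insertionsPerClone = config$sim_insertions_per_clone,
      cisRate = config$sim_cis_rate, transRate = config$sim_trans_rate,
      cisDecayLambda = config$sim_cis_decay_lambda,
      variantSpacing = config$sim_variant_spacing, seed = seed)
    writeTruth(sim, file.path(outDir, "truth"))
    counts$insertions <- nrow(insertions(sim))
    counts$events <- nrow(creEvents(sim))
  }
  needSim <- function() {
    if (is.null(sim)) stop("upstream simulate stage missing; run it first")
    sim
  }

  mapped <- NULL
  if ("map" %in% stages) {
    sim <- needSim()
    obs <- lapply(1:2, function(r) {
      reads <- emitIvtReads(sim, depthPerSide = config$sim_ivt_depth_per_side,
                            readLen = config$sim_ivt_read_len,
                            errRate = config$sim_ivt_err_rate,
                            seed = deriveSeed(seed, 10L + r))
      placeIvtReads(reads, sim@genome, sim@design)
    })
    parental <- emitAmpliconReads(sim, includeDerivatives = FALSE,
                                  moleculesPerCassette = config$sim_amplicon_molecules,
                                  readsPerUmi = config$sim_amplicon_reads_per_umi,
                                  seed = deriveSeed(seed, 20L))
    parentalCounts <- averageParentalCounts(
      countAmpliconPairs(parental), scale = config$cpm_scale)
    mapped <- mapInsertions(obs, parentalCounts, config)
    writeTsv(mapped$insertions, file.path(outDir, "mapped_insertions.tsv"))
    writeTsv(mapped$unpaired, file.path(outDir, "unpaired_clusters.tsv"))
    counts$mapped_insertions <- nrow(mapped$insertions)
  }

  calls <- NULL
  if ("call" %in% stages) {
    sim <- needSim()
    if (is.null(mapped)) stop("upstream map stage missing; run it first")
    post <- emitAmpliconReads(sim, includeDerivatives = TRUE,
                              moleculesPerCassette = config$sim_amplicon_molecules,
                              readsPerUmi = config$sim_amplicon_reads_per_umi,
                              chimeraRate = config$sim_chimera_rate,
                              sampleId = "cre",
                              seed = deriveSeed(seed, 21L))
    pc <- countAmpliconPairs(post)
    calls <- callRearrangements(pc, mapped$insertions,
                                minUmi = config$rearrangement_min_umi)
    writeTsv(calls, file.path(outDir, "rearrangements.tsv"))
    if (nrow(calls))
      writeCallsBedpe(calls, file.path(outDir, "rearrangements.bedpe"))
    counts$rearrangements <- nrow(calls)
  }

  if ("validate" %in% stages) {
    sim <- needSim()
    if (is.null(calls)) stop("upstream call stage missing; run it first")
    postIvt <- emitIvtReads(sim, depthPerSide = config$sim_ivt_depth_per_side,
                            errRate = config$sim_ivt_err_rate,
                            includeDerivatives = TRUE,
                            seed = deriveSeed(seed, 30L))
    postObs <- placeIvtReads(postIvt, sim@genome, sim@design)
    postClusters <- clusterObservations(filterAlignments(postObs),
                                        config$levenshtein_budget)
    parIvt <- emitIvtReads(sim, depthPerSide = config$sim_ivt_depth_per_side,
                           errRate = config$sim_ivt_err_rate,
                           includeDerivatives = FALSE,
                           seed = deriveSeed(seed, 31L))
    parObs <- placeIvtReads(parIvt, sim@genome, sim@design)
    parClusters <- clusterObservations(filterAlignments(parObs),
                                       config$levenshtein_budget)
    validated <- validateWithIvt(calls, postClusters, parClusters)
    writeTsv(validated, file.path(outDir, "rearrangements_validated.tsv"))
    counts$ivt_supported <- sum(validated$ivt_supported)
  }

  if ("sc" %in% stages) {
    sim <- needSim()
    if (is.null(mapped)) stop("upstream map stage missing; run it first")
    sc <- emitT7SingleCellReads(sim, nCells = config$sim_n_cells,
                                captureRate = config$sim_capture_rate,
                                umiDepth = config$sim_umi_depth,
                                ambientRate = config$sim_ambient_rate,
                                doubletRate = config$sim_doublet_rate,
                                seed = deriveSeed(seed, 40L))
    keep <- qcCells(sc$qc, config$qc_min_umi, config$qc_mito_range,
                    config$qc_doublet_max)
    recs <- filterChimericUmis(sc$reads[sc$reads$cell_bc %in% keep, ],
                               config$chimera_min_share)
    mat <- buildBcCellMatrix(collapseUmis(recs))
    writeBcCellMatrix(mat, file.path(outDir, "t7_matrix"))
    res <- iterateClonotypeRounds(mat, config,
                                  seed = deriveSeed(seed, 41L))
    writeTsv(clonotypeInfo(res$clonotypes),
             file.path(outDir, "clonotypes.tsv"))
    writeTsv(clonotypePairs(res$clonotypes),
             file.path(outDir, "clonotype_pairs.tsv"))
    writeTsv(res$assignments, file.path(outDir, "cell_assignments.tsv"))
    pr <- prThresholdAnalysis(mat, res$assignments, res$clonotypes)
    writeTsv(pr, file.path(outDir, "pr_thresholds.tsv"))
    scCalls <- callScRearrangements(mat, mapped$insertions,
                                    res$clonotypes, res$assignments,
                                    minUmi = config$assign_min_umi)
    writeTsv(scCalls$calls, file.path(outDir, "sc_rearrangements.tsv"))
    counts$clonotypes <- nrow(clonotypeInfo(res$clonotypes))
    counts$assigned_cells <- sum(res$assignments$status == "assigned")
    counts$sc_rearrangements <- nrow(scCalls$calls)
  }

  cfgFile <- file.path(outDir, "config.yaml")
  saveConfig(config, cfgFile)
  manifest <- list(
    tool = "shuffleseq",
    version = as.character(utils::packageVersion("shuffleseq")),
    config_hash = unname(tools::md5sum(cfgFile)),
    seed = seed,
    stages = stages,
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
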