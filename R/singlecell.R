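#' Filter likely chimeric UMIs
#'
#' Within each (cell barcode, UMI), read counts are tallied per
#' (bc1, bc2, capture side) combination; combinations whose share of the
#' UMI's reads falls below `minShare` are discarded as chimeric.
#'
#' @param records read-level T7 records (cell_bc, umi, bc1, bc2,
#'   capture_side).
#' @param minShare minimum read share (default 0.2; shares strictly below
#'   are dropped).
#' @return aggregated records with a read_count column.
#' @export
filterChimericUmis <- function(records, minShare = 0.2) {
  if (nrow(records) == 0L) {
    records$read_count <- integer(0)
    return(records)
  }
  dt <- data.table::as.data.table(records)
  agg <- dt[, .(read_count = .N),
            by = .(cell_bc, umi, bc1, bc2, capture_side)]
  agg[, share := read_count / sum(read_count), by = .(cell_bc, umi)]
  out <- as.data.frame(agg[share >= minShare][, share := NULL])
  out <- out[order(out$cell_bc, out$umi, out$bc1, out$bc2,
                   out$capture_side), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse UMIs by Hamming-1 connected components
#'
#' The UMI count of each (cell, pair, capture side) combination is the
#' number of connected components in the graph joining its UMIs at
#' Hamming distance at most 1.
#'
#' @param records aggregated T7 records from [filterChimericUmis()] (or
#'   read-level records; duplicates are handled).
#' @return data.frame with cell_bc, bc1, bc2, capture_side, umi_count.
#' @export
collapseUmis <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(cell_bc = character(0), bc1 = character(0),
                      bc2 = character(0), capture_side = character(0),
                      umi_count = integer(0), stringsAsFactors = FALSE))
  key <- paste(records$cell_bc, records$bc1, records$bc2,
               records$capture_side, sep = "\r")
  groups <- split(records$umi, key)
  counts <- vapply(groups, function(u) {
    u <- unique(u)
    if (length(u) == 1L) return(1L)
    max(componentsUnderThreshold(hammingDistance(u), 1L))
  }, integer(1))
  parts <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(
    cell_bc = vapply(parts, `[`, character(1), 1L),
    bc1 = vapply(parts, `[`, character(1), 2L),
    bc2 = vapply(parts, `[`, character(1), 3L),
    capture_side = vapply(parts, `[`, character(1), 4L),
    umi_count = unname(counts), stringsAsFactors = FALSE)
  out[order(out$cell_bc, out$bc1, out$bc2, out$capture_side), ,
      drop = FALSE]
}

#' Build the barcode-pair by cell UMI matrix
#'
#' Sums UMI counts of the same pair in the same cell over the two capture
#' sides and stores the result as a sparse matrix (rows `bc1|bc2`,
#' columns cell barcodes).
#'
#' @param umiCounts output of [collapseUmis()].
#' @return a [Matrix::sparseMatrix()] (dgCMatrix).
#' @export
buildBcCellMatrix <- function(umiCounts) {
  if (nrow(umiCounts) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(0L, 0L)))
  pair <- pairKey(umiCounts$bc1, umiCounts$bc2)
  rows <- sort(unique(pair))
  cols <- sort(unique(umiCounts$cell_bc))
  Matrix::sparseMatrix(i = match(pair, rows),
                       j = match(umiCounts$cell_bc, cols),
                       x = umiCounts$umi_count,
                       dims = c(length(rows), length(cols)),
                       dimnames = list(rows, cols))
}

#' Quality-filter cells on transcriptome metrics
#'
#' Retains cell barcodes with more than `minUmi` transcriptome UMIs, a
#' mitochondrial fraction within `mitoRange` percent (inclusive) and a
#' doublet score below `maxDoublet`.
#'
#' @param qc QC table (cell_bc, transcriptome_umis, mito_fraction,
#'   doublet_score).
#' @param minUmi,mitoRange,maxDoublet thresholds (defaults 1000,
#'   `c(1, 12)` percent, 0.4).
#' @return character vector of retained cell barcodes.
#' @export
qcCells <- function(qc, minUmi = 1000, mitoRange = c(1, 12),
                    maxDoublet = 0.4) {
  keep <- qc$transcriptome_umis > minUmi &
    qc$mito_fraction >= mitoRange[1L] & qc$mito_fraction <= mitoRange[2L] &
    qc$doublet_score < maxDoublet
  qc$cell_bc[keep]
}

#' Reconstruct clonotypes de novo from the barcode-by-cell matrix
#'
#' Pipeline: (i) entries below `minUmiPerPair` UMIs are zeroed; (ii) cells
#' and pairs with fewer than `minCellTotal` / `minPairTotal` total UMIs
#' are removed; (iii) cells are embedded by library-size normalisation
#' (scaled to `normScale` per cell, log-free), principal components
#' (up to 100), and a `kNeighbors`-nearest-neighbour graph partitioned by
#' Leiden modularity communities at resolution 1; (iv) within each
#' community, pair detection fractions are rank-ordered and cut at the
#' first rank where the fraction ratio to the next rank exceeds
#' `rankRatioCut` (candidates without such an inflection are rejected);
#' (v) candidates need a maximum detection fraction above
#' `minMaxDetection` and more than `minPairs - 1` pairs; (vi) candidates
#' whose pair co-detection matrix splits into two blocks with cross-block
#' co-detection under 10% of within-block are flagged as doublet
#' clonotypes and dropped; (vii) near-duplicate candidates are merged by
#' intersecting members connected at Jaccard > `jaccardConnect`.
#'
#' @param mat sparse pair-by-cell matrix from [buildBcCellMatrix()].
#' @param minUmiPerPair,minCellTotal,minPairTotal,kNeighbors,resolution,
#'   rankRatioCut,minMaxDetection,minPairs,jaccardConnect,normScale
#'   pipeline parameters (defaults follow the package configuration).
#' @param provenance provenance label for accepted clonotypes.
#' @param seed integer seed for the community detection.
#' @return a [ClonotypeSet-class].
#' @export
reconstructClonotypes <- function(mat, minUmiPerPair = 3L,
                                  minCellTotal = 20L, minPairTotal = 20L,
                                  kNeighbors = 10L, resolution = 1,
                                  rankRatioCut = 1.5,
                                  minMaxDetection = 0.5, minPairs = 7L,
                                  jaccardConnect = 0.1, normScale = 1e4,
                                  provenance = "de_novo_round1",
                                  seed = 1L) {
  m <- mat
  m@x[m@x < minUmiPerPair] <- 0
  m <- Matrix::drop0(m)
  keepCells <- Matrix::colSums(m) >= minCellTotal
  keepPairs <- Matrix::rowSums(m) >= minPairTotal
  m <- m[keepPairs, keepCells, drop = FALSE]
  if (ncol(m) <= kNeighbors)
    stop("fewer cells than the neighbourhood size after filtering")
  ## embedding: relative counts, PCA, kNN graph, Leiden communities
  norm <- m %*% Matrix::Diagonal(x = normScale / Matrix::colSums(m))
  npc <- min(100L, nrow(m) - 1L, ncol(m) - 1L)
  pcs <- prcomp(as.matrix(Matrix::t(norm)), rank. = npc, center = TRUE)$x
  d <- as.matrix(stats::dist(pcs))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(r) order(r)[seq_len(kNeighbors)])
  edges <- rbind(rep(seq_len(ncol(m)), each = kNeighbors), as.vector(nn))
  g <- igraph::simplify(igraph::graph_from_edgelist(t(edges),
                                                    directed = FALSE))
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
  member <- igraph::membership(comm)

  detected <- m > 0
  candidates <- list()
  for (cm in sort(unique(member))) {
    cells <- which(member == cm)
    frac <- Matrix::rowSums(detected[, cells, drop = FALSE]) / length(cells)
    ord <- order(-frac, rownames(m))
    fr <- frac[ord]
    if (length(fr) < 2L || fr[1L] == 0) next
    ## ratios over the full ranking; the boundary to an undetected pair
    ## divides by zero and registers as an infinite-fold inflection
    ratio <- fr[-length(fr)] / fr[-1L]
    cut <- which(ratio > rankRatioCut)
    if (length(cut) == 0L) next  # no inflection: reject candidate
    nKeep <- cut[1L]
    pairs <- names(fr)[seq_len(nKeep)]
    if (fr[1L] <= minMaxDetection || length(pairs) < minPairs) next
    if (isDoubletClonotype(detected[pairs, cells, drop = FALSE])) next
    candidates[[length(candidates) + 1L]] <-
      list(pairs = pairs, maxDet = fr[1L])
  }
  if (length(candidates) == 0L)
    return(emptyClonotypeSet())
  ## merge near-duplicates through the Jaccard graph
  nC <- length(candidates)
  adj <- matrix(FALSE, nC, nC)
  for (i in seq_len(nC)) for (j in seq_len(nC))
    adj[i, j] <- jaccardIndex(candidates[[i]]$pairs,
                              candidates[[j]]$pairs) > jaccardConnect
  compId <- componentsUnderThreshold(ifelse(adj, 0, 99), 0)
  infoRows <- list(); pairRows <- list()
  for (k in sort(unique(compId))) {
    members <- which(compId == k)
    pairs <- Reduce(intersect, lapply(members, function(i)
      candidates[[i]]$pairs))
    if (length(pairs) < minPairs) next
    id <- sprintf("ct%03d", length(infoRows) + 1L)
    infoRows[[id]] <- data.frame(
      clonotype_id = id, provenance = provenance,
      n_pairs = length(pairs),
      max_detection_fraction = max(vapply(members, function(i)
        candidates[[i]]$maxDet, numeric(1))),
      stringsAsFactors = FALSE)
    bc <- strsplit(pairs, "|", fixed = TRUE)
    pairRows[[id]] <- data.frame(
      clonotype_id = id,
      bc1 = vapply(bc, `[`, character(1), 1L),
      bc2 = vapply(bc, `[`, character(1), 2L),
      stringsAsFactors = FALSE)
  }
  if (length(infoRows) == 0L) return(emptyClonotypeSet())
  new("ClonotypeSet",
      info = do.call(rbind, c(infoRows, list(make.row.names = FALSE))),
      pairs = do.call(rbind, c(pairRows, list(make.row.names = FALSE))))
}

## Spectral bipartition of the pair co-detection matrix; a clonotype is a
## doublet artifact when its pairs split into two blocks that are almost
## never co-detected across blocks.
isDoubletClonotype <- function(det, crossFractionCut = 0.1) {
  co <- as.matrix(det %*% Matrix::t(det))
  n <- nrow(co)
  if (n < 4L) return(FALSE)
  deg <- rowSums(co)
  lap <- diag(deg) - co
  ev <- eigen(lap, symmetric = TRUE)
  fiedler <- ev$vectors[, n - 1L]
  a <- fiedler >= 0
  if (sum(a) < 2L || sum(!a) < 2L) return(FALSE)
  within <- mean(c(co[a, a][upper.tri(co[a, a])],
                   co[!a, !a][upper.tri(co[!a, !a])]))
  cross <- mean(co[a, !a])
  if (within == 0) return(FALSE)
  cross / within < crossFractionCut
}

emptyClonotypeSet <- function() {
  new("ClonotypeSet",
      info = data.frame(clonotype_id = character(0),
                        provenance = character(0), n_pairs = integer(0),
                        max_detection_fraction = numeric(0),
                        stringsAsFactors = FALSE),
      pairs = data.frame(clonotype_id = character(0), bc1 = character(0),
                         bc2 = character(0), stringsAsFactors = FALSE))
}

#' Merge de novo clonotypes with bulk-derived clonotypes
#'
#' Bulk clonotypes matching a de novo clonotype at Jaccard index above
#' `jaccardBulk` are treated as the same clonotype (the de novo member
#' set is kept, provenance becomes `merged`); non-overlapping bulk
#' clonotypes are appended with provenance `bulk`.
#'
#' @param deNovo a [ClonotypeSet-class].
#' @param bulkPairs data.frame (clone_id, bc1, bc2) of bulk clonotypes.
#' @param jaccardBulk merge threshold (default 0.05).
#' @return unified [ClonotypeSet-class].
#' @export
mergeWithBulk <- function(deNovo, bulkPairs, jaccardBulk = 0.05) {
  if (is.null(bulkPairs) || nrow(bulkPairs) == 0L) return(deNovo)
  deSets <- clonotypePairSets(deNovo)
  info <- clonotypeInfo(deNovo)
  pairs <- clonotypePairs(deNovo)
  for (cl in unique(bulkPairs$clone_id)) {
    b <- bulkPairs[bulkPairs$clone_id == cl, , drop = FALSE]
    bSet <- pairKey(b$bc1, b$bc2)
    jac <- vapply(deSets, jaccardIndex, numeric(1), b = bSet)
    if (length(jac) && any(jac > jaccardBulk)) {
      hit <- names(deSets)[which.max(jac)]
      info$provenance[info$clonotype_id == hit] <- "merged"
    } else {
      id <- sprintf("bulk_%s", cl)
      info <- rbind(info, data.frame(
        clonotype_id = id, provenance = "bulk", n_pairs = length(bSet),
        max_detection_fraction = NA_real_, stringsAsFactors = FALSE))
      pairs <- rbind(pairs, data.frame(clonotype_id = id, bc1 = b$bc1,
                                       bc2 = b$bc2,
                                       stringsAsFactors = FALSE))
    }
  }
  new("ClonotypeSet", info = info, pairs = pairs)
}

#' Assign cells to clonotypes by barcode-1 precision and recall
#'
#' For each cell, the set of distinct first barcodes detected at
#' `minUmi` or more UMIs is compared to every clonotype's barcode-1 set:
#' precision is the fraction of the cell's barcodes belonging to the
#' clonotype and recall the fraction of the clonotype's barcodes seen in
#' the cell. The clonotype with the highest precision wins; the cell is
#' assigned iff top recall exceeds `minRecall` and top precision exceeds
#' `minPrecision`, is discarded as a probable doublet when the
#' second-best clonotype's recall exceeds `maxSecondRecall`, and is
#' labelled `low_capture` when the top recall is at or below `minRecall`.
#'
#' @param mat pair-by-cell matrix.
#' @param clonotypes a [ClonotypeSet-class].
#' @param minUmi per-pair UMI threshold (default 2).
#' @param minRecall,minPrecision,maxSecondRecall assignment thresholds.
#' @return CellAssignment data.frame.
#' @export
assignCells <- function(mat, clonotypes, minUmi = 2L, minRecall = 0.1,
                        minPrecision = 0.75, maxSecondRecall = 0.1) {
  info <- clonotypeInfo(clonotypes)
  cp <- clonotypePairs(clonotypes)
  ctBc1 <- lapply(split(cp$bc1, cp$clonotype_id), unique)
  ctBc1 <- ctBc1[info$clonotype_id]
  rowBc1 <- sub("\\|.*$", "", rownames(mat))
  out <- data.frame(cell_bc = colnames(mat),
                    clonotype_id = NA_character_,
                    top_precision = NA_real_, top_recall = NA_real_,
                    second_recall = NA_real_, status = "low_capture",
                    stringsAsFactors = FALSE)
  if (length(ctBc1) == 0L || ncol(mat) == 0L) return(out)
  detected <- mat >= minUmi
  for (c in seq_len(ncol(mat))) {
    cellBc1 <- unique(rowBc1[detected[, c]])
    if (length(cellBc1) == 0L) next
    prec <- vapply(ctBc1, function(s) mean(cellBc1 %in% s), numeric(1))
    rec <- vapply(ctBc1, function(s) mean(s %in% cellBc1), numeric(1))
    ord <- order(-prec, -rec, names(ctBc1))
    top <- ord[1L]
    secondRecall <- if (length(ord) > 1L) max(rec[ord[-1L]]) else 0
    out$top_precision[c] <- prec[top]
    out$top_recall[c] <- rec[top]
    out$second_recall[c] <- secondRecall
    if (rec[top] > minRecall && prec[top] > minPrecision &&
        secondRecall <= maxSecondRecall) {
      out$clonotype_id[c] <- names(ctBc1)[top]
      out$status[c] <- "assigned"
    } else if (rec[top] > minRecall && prec[top] > minPrecision) {
      out$status[c] <- "ambiguous_doublet"
    } else if (rec[top] <= minRecall) {
      out$status[c] <- "low_capture"
    } else {
      out$status[c] <- "unassigned"
    }
  }
  out
}

#' Iterative clonotype discovery and assignment
#'
#' Round 1 reconstructs clonotypes from all cells and merges them with
#' bulk clonotypes when supplied; assignable cells are then removed and
#' reconstruction repeats on the remainder (later rounds get provenance
#' `de_novo_round2plus`), until a round adds no new clonotype. New
#' clonotypes duplicating an existing one at Jaccard > 0.95 are dropped.
#'
#' @param mat pair-by-cell matrix.
#' @param config a [shuffleConfig()] list.
#' @param bulkPairs optional bulk clonotype table (clone_id, bc1, bc2).
#' @param maxRounds safety cap on iterations.
#' @param seed integer seed.
#' @return list with `clonotypes` (final [ClonotypeSet-class]),
#'   `assignments` (final assignment table) and `rounds` used.
#' @export
iterateClonotypeRounds <- function(mat, config = shuffleConfig(),
                                   bulkPairs = NULL, maxRounds = 5L,
                                   seed = 1L) {
  reconstruct <- function(m, prov, sd) reconstructClonotypes(
    m, minUmiPerPair = config$clonotype_min_umi_per_pair,
    minCellTotal = config$min_cell_total_umi,
    minPairTotal = config$min_pair_total_umi,
    kNeighbors = config$knn_neighbors,
    resolution = config$cluster_resolution,
    rankRatioCut = config$rank_ratio_cut,
    minMaxDetection = config$min_max_detection_fraction,
    minPairs = config$min_clonotype_pairs,
    jaccardConnect = config$jaccard_connect,
    normScale = config$sc_norm_scale, provenance = prov, seed = sd)
  current <- reconstruct(mat, "de_novo_round1", seed)
  current <- mergeWithBulk(current, bulkPairs, config$jaccard_bulk)
  remaining <- mat
  round <- 1L
  repeat {
    assignments <- assignCells(remaining, current,
                               minUmi = config$assign_min_umi,
                               minRecall = config$assign_min_recall,
                               minPrecision = config$assign_min_precision,
                               maxSecondRecall = config$doublet_second_recall)
    assigned <- assignments$cell_bc[assignments$status == "assigned"]
    remaining <- remaining[, !(colnames(remaining) %in% assigned),
                           drop = FALSE]
    round <- round + 1L
    if (round > maxRounds || ncol(remaining) <= config$knn_neighbors) break
    extra <- tryCatch(
      reconstruct(remaining, "de_novo_round2plus", seed + round),
      error = function(e) emptyClonotypeSet())
    extra <- dropKnownClonotypes(extra, current,
                                 jaccardDuplicate = config$jaccard_merge)
    if (nrow(clonotypeInfo(extra)) == 0L) break
    current <- appendClonotypes(current, extra)
  }
  finalAssign <- assignCells(mat, current,
                             minUmi = config$assign_min_umi,
                             minRecall = config$assign_min_recall,
                             minPrecision = config$assign_min_precision,
                             maxSecondRecall = config$doublet_second_recall)
  list(clonotypes = current, assignments = finalAssign, rounds = round - 1L)
}

dropKnownClonotypes <- function(candidate, existing, jaccardDuplicate = 0.95) {
  if (nrow(clonotypeInfo(candidate)) == 0L) return(candidate)
  exSets <- clonotypePairSets(existing)
  keep <- vapply(clonotypePairSets(candidate), function(s) {
    !any(vapply(exSets, jaccardIndex, numeric(1), b = s) > jaccardDuplicate)
  }, logical(1))
  ids <- names(keep)[keep]
  new("ClonotypeSet",
      info = candidate@info[candidate@info$clonotype_id %in% ids, ,
                            drop = FALSE],
      pairs = candidate@pairs[candidate@pairs$clonotype_id %in% ids, ,
                              drop = FALSE])
}

appendClonotypes <- function(a, b) {
  bInfo <- clonotypeInfo(b); bPairs <- clonotypePairs(b)
  newIds <- paste0(bInfo$clonotype_id, "_n",
                   nrow(clonotypeInfo(a)) + seq_len(nrow(bInfo)))
  bPairs$clonotype_id <- newIds[match(bPairs$clonotype_id,
                                      bInfo$clonotype_id)]
  bInfo$clonotype_id <- newIds
  new("ClonotypeSet", info = rbind(clonotypeInfo(a), bInfo),
      pairs = rbind(clonotypePairs(a), bPairs))
}

#' Precision-recall analysis across UMI thresholds
#'
#' For each UMI threshold, the pairs detected in every assigned cell are
#' compared to the pairs of its assigned clonotype; precision and recall
#' are averaged over assigned cells (cells with no detected pair at a
#' threshold contribute recall 0 and are skipped for precision).
#'
#' @param mat pair-by-cell matrix.
#' @param assignments assignment table from [assignCells()].
#' @param clonotypes a [ClonotypeSet-class].
#' @param thresholds integer vector of UMI thresholds (default 1:10).
#' @return data.frame (threshold, mean_precision, mean_recall, n_cells).
#' @export
prThresholdAnalysis <- function(mat, assignments, clonotypes,
                                thresholds = 1:10) {
  sets <- clonotypePairSets(clonotypes)
  assigned <- assignments[assignments$status == "assigned", , drop = FALSE]
  res <- lapply(thresholds, function(t) {
    prec <- c(); rec <- c()
    for (k in seq_len(nrow(assigned))) {
      cell <- assigned$cell_bc[k]
      ct <- sets[[assigned$clonotype_id[k]]]
      det <- rownames(mat)[mat[, cell] >= t]
      rec <- c(rec, mean(ct %in% det))
      if (length(det)) prec <- c(prec, mean(det %in% ct))
    }
    data.frame(threshold = t,
               mean_precision = if (length(prec)) mean(prec) else NA_real_,
               mean_recall = if (length(rec)) mean(rec) else NA_real_,
               n_cells = length(rec))
  })
  do.call(rbind, res)
}

#' Call rearrangements in single cells with a congruence filter
#'
#' Applies the bulk novel-pair rules per assigned cell: pairs detected at
#' `minUmi` or more UMIs whose two barcodes are in the bonafide insertion
#' list but never co-occur in the parental set. A call is congruent iff
#' both contributing insertions' parental pairs belong to the cell's
#' assigned clonotype; incongruent calls are flagged as probable ambient
#' contamination and excluded from the validated set.
#'
#' @param mat pair-by-cell matrix.
#' @param bonafide bonafide insertion table.
#' @param clonotypes a [ClonotypeSet-class].
#' @param assignments assignment table.
#' @param minUmi per-cell UMI threshold (default 2).
#' @param parentalPairs optional parental pair keys; defaults to the
#'   bonafide pairs.
#' @return list with `calls` (congruent, classified), `ambient`
#'   (incongruent calls), `perCell` (calls per cell) and `perSv` (cells
#'   per rearrangement).
#' @export
callScRearrangements <- function(mat, bonafide, clonotypes, assignments,
                                 minUmi = 2L, parentalPairs = NULL) {
  if (is.null(parentalPairs))
    parentalPairs <- pairKey(bonafide$bc1, bonafide$bc2)
  sets <- clonotypePairSets(clonotypes)
  assigned <- assignments[assignments$status == "assigned", , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(assigned))) {
    cell <- assigned$cell_bc[k]
    det <- rownames(mat)[mat[, cell] >= minUmi]
    novel <- setdiff(det, parentalPairs)
    if (length(novel) == 0L) next
    bc <- strsplit(novel, "|", fixed = TRUE)
    b1 <- vapply(bc, `[`, character(1), 1L)
    b2 <- vapply(bc, `[`, character(1), 2L)
    i <- match(b1, bonafide$bc1)
    j <- match(b2, bonafide$bc2)
    ok <- !is.na(i) & !is.na(j)
    if (!any(ok)) next
    ctPairs <- sets[[assigned$clonotype_id[k]]]
    parentA <- pairKey(bonafide$bc1[i[ok]], bonafide$bc2[i[ok]])
    parentB <- pairKey(bonafide$bc1[j[ok]], bonafide$bc2[j[ok]])
    congruent <- parentA %in% ctPairs & parentB %in% ctPairs
    novelCounts <- data.frame(bc1 = b1[ok], bc2 = b2[ok],
                              umi_count = mat[novel[ok], cell],
                              stringsAsFactors = FALSE)
    cls <- classifySv(novelCounts, bonafide[i[ok], , drop = FALSE],
                      bonafide[j[ok], , drop = FALSE])
    cls$cell_bc <- cell
    cls$clonotype_id <- assigned$clonotype_id[k]
    cls$congruent <- congruent
    rows[[length(rows) + 1L]] <- cls
  }
  all <- if (length(rows)) do.call(rbind, rows) else
    cbind(classifySv(data.frame(bc1 = character(0), bc2 = character(0)),
                     bonafide[0L, ], bonafide[0L, ]),
          cell_bc = character(0), clonotype_id = character(0),
          congruent = logical(0))
  calls <- all[all$congruent, , drop = FALSE]
  ambient <- all[!all$congruent, , drop = FALSE]
  rownames(calls) <- rownames(ambient) <- NULL
  perCell <- if (nrow(calls)) table(calls$cell_bc) else table(character(0))
  perSv <- if (nrow(calls)) table(pairKey(calls$bc1, calls$bc2)) else
    table(character(0))
  list(calls = calls, ambient = ambient, perCell = perCell, perSv = perSv)
}
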