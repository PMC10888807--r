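## deterministic distinct barcodes: 20-nt strings over a 4-letter code
codeBc <- function(i, width = 20L) {
  digits <- integer(0)
  x <- i
  for (k in 1:width) { digits <- c(digits, x %% 4L); x <- x %/% 4L }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

toyClonotypes <- function(nPairs = 30L, id = "ct001") {
  pairs <- data.frame(clonotype_id = id,
                      bc1 = vapply(seq_len(nPairs), codeBc, character(1)),
                      bc2 = vapply(seq_len(nPairs) + 1000L, codeBc,
                                   character(1)),
                      stringsAsFactors = FALSE)
  new("ClonotypeSet",
      info = data.frame(clonotype_id = id, provenance = "bulk",
                        n_pairs = nPairs, max_detection_fraction = NA_real_,
                        stringsAsFactors = FALSE),
      pairs = pairs)
}

test_that("a candidate cut after three ranks is rejected for having too few pairs", {
  set.seed(5)
  nCells <- 60L
  pairs <- c("P1|x", "P2|x", "P3|x", "P4|x")
  frac <- c(0.9, 0.88, 0.85, 0.2)
  mat <- Matrix::Matrix(0, 4, nCells, sparse = TRUE,
                        dimnames = list(pairs, sprintf("c%02d", 1:nCells)))
  for (p in 1:4) {
    on <- sample(nCells, round(frac[p] * nCells))
    mat[p, on] <- 10
  }
  out <- reconstructClonotypes(methods::as(mat, "CsparseMatrix"),
                               minCellTotal = 5L, minPairTotal = 5L)
  expect_equal(nrow(clonotypeInfo(out)), 0L)
})

test_that("clonotype recovery on a simulated population is exact and near-duplicates merge", {
  sim <- smallSim(nClones = 6, insertionsPerClone = 12, seed = 23)
  sc <- emitT7SingleCellReads(sim, nCells = 300, captureRate = 0.7,
                              ambientRate = 0.02, doubletRate = 0.03,
                              seed = 24)
  mat <- buildBcCellMatrix(collapseUmis(filterChimericUmis(sc$reads)))
  res <- iterateClonotypeRounds(mat, shuffleConfig(), seed = 25)
  truthSets <- split(paste(insertions(sim)$bc1, insertions(sim)$bc2,
                           sep = "|"), insertions(sim)$clone_id)
  recSets <- clonotypePairSets(res$clonotypes)
  jac <- vapply(truthSets, function(ts)
    max(vapply(recSets, function(rs)
      length(intersect(rs, ts)) / length(union(rs, ts)), numeric(1))),
    numeric(1))
  expect_true(all(jac == 1))
  expect_equal(length(recSets), length(truthSets))
})

test_that("bulk merging keeps matching clonotypes once and appends disjoint ones", {
  denovo <- toyClonotypes(10)
  bulkSame <- data.frame(clone_id = "bk1",
                         bc1 = clonotypePairs(denovo)$bc1,
                         bc2 = clonotypePairs(denovo)$bc2)
  merged <- mergeWithBulk(denovo, bulkSame)
  expect_equal(nrow(clonotypeInfo(merged)), 1L)
  expect_identical(clonotypeInfo(merged)$provenance, "merged")
  bulkNew <- data.frame(clone_id = "bk2",
                        bc1 = vapply(101:110, codeBc, character(1)),
                        bc2 = vapply(2101:2110, codeBc, character(1)))
  merged2 <- mergeWithBulk(denovo, bulkNew)
  expect_equal(nrow(clonotypeInfo(merged2)), 2L)
  expect_true("bulk" %in% clonotypeInfo(merged2)$provenance)
})

test_that("cell assignment thresholds implement precision/recall and doublet rules", {
  ct <- toyClonotypes(30)
  ## a cell detecting 10 barcodes, 9 of them from the clonotype:
  ## precision 0.9, recall 0.3 -> assigned
  cellPairs <- c(paste0(clonotypePairs(ct)$bc1[1:9], "|",
                        clonotypePairs(ct)$bc2[1:9]),
                 paste0(codeBc(999), "|", codeBc(1999)))
  mat <- Matrix::sparseMatrix(
    i = seq_along(cellPairs), j = rep(1L, length(cellPairs)),
    x = rep(3, length(cellPairs)),
    dims = c(length(cellPairs), 1L),
    dimnames = list(cellPairs, "cellA"))
  asg <- assignCells(mat, ct)
  expect_identical(asg$status, "assigned")
  expect_equal(asg$top_precision, 0.9)
  expect_equal(asg$top_recall, 0.3)
  ## low precision is not assigned
  few <- c(paste0(clonotypePairs(ct)$bc1[1:6], "|",
                  clonotypePairs(ct)$bc2[1:6]),
           vapply(300:303, function(i)
             paste0(codeBc(i), "|", codeBc(i + 5000)), character(1)))
  mat2 <- Matrix::sparseMatrix(
    i = seq_along(few), j = rep(1L, length(few)), x = rep(3, length(few)),
    dims = c(length(few), 1L), dimnames = list(few, "cellB"))
  asg2 <- assignCells(mat2, ct)
  expect_equal(asg2$top_precision, 0.6)
  expect_false(asg2$status == "assigned")
  ## a strong second-best recall flags a probable doublet
  ct2 <- toyClonotypes(10, id = "ct002")
  both <- new("ClonotypeSet",
              info = rbind(clonotypeInfo(toyClonotypes(10)),
                           clonotypeInfo(ct2)),
              pairs = rbind(clonotypePairs(toyClonotypes(10)),
                            transform(clonotypePairs(ct2),
                                      bc1 = vapply(501:510, codeBc,
                                                   character(1)))))
  dblPairs <- c(paste0(clonotypePairs(both)$bc1[1:10], "|",
                       clonotypePairs(both)$bc2[1:10]),
                paste0(clonotypePairs(both)$bc1[11:13], "|",
                       clonotypePairs(both)$bc2[11:13]))
  mat3 <- Matrix::sparseMatrix(
    i = seq_along(dblPairs), j = rep(1L, length(dblPairs)),
    x = rep(3, length(dblPairs)), dims = c(length(dblPairs), 1L),
    dimnames = list(dblPairs, "cellC"))
  asg3 <- assignCells(mat3, both)
  expect_identical(asg3$status, "ambiguous_doublet")
  expect_gt(asg3$second_recall, 0.1)
})

test_that("assignment is invariant to row and column permutation of the matrix", {
  sim <- smallSim(nClones = 4, insertionsPerClone = 10, seed = 33)
  sc <- emitT7SingleCellReads(sim, nCells = 120, seed = 34)
  mat <- buildBcCellMatrix(collapseUmis(filterChimericUmis(sc$reads)))
  ct <- new("ClonotypeSet",
            info = data.frame(clonotype_id = unique(insertions(sim)$clone_id),
                              provenance = "bulk",
                              n_pairs = 10L,
                              max_detection_fraction = NA_real_,
                              stringsAsFactors = FALSE),
            pairs = data.frame(clonotype_id = insertions(sim)$clone_id,
                               bc1 = insertions(sim)$bc1,
                               bc2 = insertions(sim)$bc2,
                               stringsAsFactors = FALSE))
  a1 <- assignCells(mat, ct)
  set.seed(2)
  perm <- mat[sample(nrow(mat)), sample(ncol(mat))]
  a2 <- assignCells(perm, ct)
  a2 <- a2[match(a1$cell_bc, a2$cell_bc), ]
  rownames(a2) <- NULL
  expect_identical(a1, a2)
})

test_that("precision is perfect and recall non-increasing without noise; ambient spikes depress only the 1-UMI level", {
  sim <- smallSim(nClones = 4, insertionsPerClone = 12, seed = 43)
  clean <- emitT7SingleCellReads(sim, nCells = 150, ambientRate = 0,
                                 doubletRate = 0, seed = 44)
  mat <- buildBcCellMatrix(collapseUmis(filterChimericUmis(clean$reads)))
  cfg <- shuffleConfig()
  res <- iterateClonotypeRounds(mat, cfg, seed = 45)
  pr <- prThresholdAnalysis(mat, res$assignments, res$clonotypes, 1:6)
  expect_true(all(pr$mean_precision == 1))
  expect_true(all(diff(pr$mean_recall) <= 1e-12))
  ## ambient-spiked: precision non-decreasing, strictly better at 2 UMIs
  noisy <- emitT7SingleCellReads(sim, nCells = 150, ambientRate = 0.05,
                                 doubletRate = 0, seed = 46)
  nmat <- buildBcCellMatrix(collapseUmis(filterChimericUmis(noisy$reads)))
  nres <- iterateClonotypeRounds(nmat, cfg, seed = 47)
  npr <- prThresholdAnalysis(nmat, nres$assignments, nres$clonotypes, 1:6)
  expect_gt(npr$mean_precision[2], npr$mean_precision[1])
  expect_true(all(diff(npr$mean_recall) <= 1e-12))
})

test_that("single-cell rearrangement calls are congruent with the assigned clone and ambient pairs are flagged", {
  sim <- smallSim(nClones = 5, insertionsPerClone = 12, cisRate = 2,
                  transRate = 0.3, seed = 53)
  sc <- emitT7SingleCellReads(sim, nCells = 250, ambientRate = 0,
                              doubletRate = 0, seed = 54)
  mat <- buildBcCellMatrix(collapseUmis(filterChimericUmis(sc$reads)))
  cfg <- shuffleConfig()
  res <- iterateClonotypeRounds(mat, cfg, seed = 55)
  scc <- callScRearrangements(mat, insertions(sim), res$clonotypes,
                              res$assignments)
  ## with no ambient reads every call is congruent
  expect_equal(nrow(scc$ambient), 0L)
  if (nrow(scc$calls)) {
    ## every call matches a truth derivative of the cell's own clone
    der <- derivativeCassettes(sim)
    det <- der[der$detectable, ]
    key <- paste(scc$calls$bc1, scc$calls$bc2)
    expect_true(all(key %in% paste(det$bc1, det$bc2)))
  }
  ## an ambient novel pair from a foreign clone is flagged and excluded
  foreign <- creEvents(sim)
  der <- derivativeCassettes(sim)
  det <- der[der$detectable, ]
  if (nrow(det)) {
    evClone <- creEvents(sim)$clone_id[match(det$event_id[1],
                                             creEvents(sim)$event_id)]
    victim <- res$assignments[res$assignments$status == "assigned" &
                                res$assignments$clonotype_id != "", ][1, ]
    spiked <- mat
    pr <- paste0(det$bc1[1], "|", det$bc2[1])
    if (!pr %in% rownames(spiked)) {
      spiked <- rbind(spiked,
                      Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           x = numeric(0),
                                           dims = c(1, ncol(spiked)),
                                           dimnames = list(pr, colnames(spiked))))
    }
    ## pick a victim cell from a different clone than the event's
    truthClone <- sc$cells$clone_id[match(colnames(spiked),
                                          sc$cells$cell_bc)]
    vcell <- which(truthClone != evClone &
                     colnames(spiked) %in%
                     res$assignments$cell_bc[res$assignments$status ==
                                               "assigned"])[1]
    spiked[pr, vcell] <- 3
    scc2 <- callScRearrangements(spiked, insertions(sim), res$clonotypes,
                                 res$assignments)
    amb <- scc2$ambient
    expect_true(any(paste(amb$bc1, amb$bc2) == paste(det$bc1[1],
                                                     det$bc2[1]) &
                      amb$cell_bc == colnames(spiked)[vcell]))
  }
})
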