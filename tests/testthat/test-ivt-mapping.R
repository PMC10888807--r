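test_that("IVT emission yields two sides per insertion and noise-free extraction is exact", {
  sim <- smallSim(nClones = 2, insertionsPerClone = 5, seed = 3)
  reads <- emitIvtReads(sim, depthPerSide = 10, errRate = 0, seed = 4)
  expect_equal(nrow(reads), 10L * 2L * 10L)
  ext <- extractIvtObservations(reads$read1)
  expect_true(all(ext$extracted))
  ## recover canonical barcodes through the layout
  ins <- insertions(sim)
  truth <- ins[match(reads$truth_unit, ins$insertion_id), ]
  top <- ext$cassette_strand == "top-CS2"
  expect_identical(ext$barcode1[top], truth$bc1[top])
  expect_identical(ext$barcode2[top], truth$bc2[top])
  expect_identical(ext$barcode1[!top], revComp(truth$bc2[!top]))
  expect_identical(ext$barcode2[!top], revComp(truth$bc1[!top]))
})

test_that("reads lacking the barcode anchors are rejected", {
  ext <- extractIvtObservations(c(strrep("A", 120),
                                  gsub("ATAAC", "AAAAA",
                                       cassetteReadTop(shuffleCassetteDesign(),
                                                       strrep("G", 20),
                                                       strrep("T", 20)))))
  expect_false(any(ext$extracted))
  expect_error(emitIvtReads(smallSim(seed = 1), readLen = 10,
                            minFlank = 30), "minFlank")
})

test_that("placed flank reads pin the junction: minus at the TTAA start, plus 4 bp beyond", {
  sim <- smallSim(nClones = 1, insertionsPerClone = 3, seed = 6)
  reads <- emitIvtReads(sim, depthPerSide = 8, errRate = 0, seed = 7)
  obs <- placeIvtReads(reads, sim@genome, sim@design)
  expect_equal(nrow(obs), nrow(reads))
  expect_true(all(obs$junction_is_ttaa))
  expect_false(any(obs$multimapped))
  pos <- alignmentPosition(obs$align_start, obs$align_end,
                           obs$genome_strand)
  ins <- insertions(sim)
  truthPos <- ins$pos[match(reads$truth_unit[match(obs$read_id,
                                                   reads$read_id)],
                            ins$insertion_id)]
  minus <- obs$genome_strand == "-"
  expect_true(all(pos[minus] == truthPos[minus] - 1L))
  expect_true(all(pos[!minus] == truthPos[!minus] + 3L))
})

test_that("clustering and pairing are invariant to observation order", {
  sim <- smallSim(nClones = 2, insertionsPerClone = 6, seed = 8)
  obs <- placeIvtReads(emitIvtReads(sim, depthPerSide = 6, errRate = 0.01,
                                    seed = 9), sim@genome, sim@design)
  obs <- filterAlignments(obs)
  cl1 <- clusterObservations(obs)
  set.seed(1)
  cl2 <- clusterObservations(obs[sample(nrow(obs)), ])
  expect_identical(cl1, cl2)
  expect_identical(pairClusters(cl1)$candidates,
                   pairClusters(cl2)$candidates)
})

test_that("alignment filter drops non-TTAA junctions, multimappers and inconclusive alleles", {
  obs <- data.frame(junction_is_ttaa = c(TRUE, FALSE, TRUE, TRUE),
                    multimapped = c(FALSE, FALSE, TRUE, FALSE),
                    allele_call = c("BL6", "BL6", "BL6", "inconclusive"))
  kept <- filterAlignments(obs)
  expect_equal(nrow(kept), 1L)
  reasons <- attr(kept, "dropReasons")
  expect_equal(as.integer(reasons[c("junction_not_ttaa", "multimapped",
                                    "inconclusive_allele")]), c(1L, 1L, 1L))
})

test_that("read allele calls follow ref/alt/noVariant/inconclusive evidence", {
  variants <- data.frame(chrom = "chr1", pos = c(105L, 112L),
                         ref = c("A", "G"), alt = c("T", "C"),
                         stringsAsFactors = FALSE)
  read <- strrep("G", 20)
  substr(read, 5, 5) <- "A"   # pos 105, matches ref
  call <- callReadAllele("chr1", 101L, 120L, read, variants)
  expect_identical(call, "BL6")  # ref at 105, ref at 112
  readAlt <- read
  substr(readAlt, 5, 5) <- "T"; substr(readAlt, 12, 12) <- "C"
  expect_identical(callReadAllele("chr1", 101L, 120L, readAlt, variants),
                   "CAST")
  mixed <- read
  substr(mixed, 12, 12) <- "C"  # ref at 105 + alt at 112
  expect_identical(callReadAllele("chr1", 101L, 120L, mixed, variants),
                   "inconclusive")
  expect_identical(callReadAllele("chr1", 200L, 260L, strrep("A", 61),
                                  variants), "noVariant")
})
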