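toyCounts <- function(bc1, bc2, reads = 10L, umis = 4L,
                      type = NULL) {
  out <- data.frame(sample_id = "s1", replicate_id = "rep1", bc1 = bc1,
                    bc2 = bc2, stringsAsFactors = FALSE)
  if (!is.null(type)) out$amplicon_type <- type
  out$read_count <- rep_len(reads, nrow(out))
  out$umi_count <- rep_len(umis, nrow(out))
  out
}

test_that("pair counting tallies reads and distinct UMIs and skips malformed records", {
  reads <- data.frame(bc1 = strrep("A", 20), bc2 = strrep("C", 20),
                      umi = rep(c("U1", "U2", "U3", "U4"),
                                times = c(4, 3, 2, 1)),
                      stringsAsFactors = FALSE)
  counts <- countAmpliconPairs(reads)
  expect_equal(counts$read_count, 10L)
  expect_equal(counts$umi_count, 4L)
  bad <- rbind(reads, data.frame(bc1 = "", bc2 = strrep("C", 20),
                                 umi = "U9"))
  counts2 <- countAmpliconPairs(bad)
  expect_equal(attr(counts2, "skipped"), 1L)
  expect_equal(counts2$read_count, 10L)
  empty <- countAmpliconPairs(reads[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("4-primer collapse sums both amplicon types and discards one-sided pairs", {
  counts <- toyCounts(bc1 = c("A", "A", "B"), bc2 = c("C", "C", "D"),
                      reads = c(3L, 5L, 7L), umis = c(2L, 3L, 4L),
                      type = c("top-CS2", "bottom-CS1", "top-CS2"))
  out <- collapseFourPrimer(counts)
  expect_equal(nrow(out), 1L)
  expect_equal(out$read_count, 8L)
  expect_equal(out$umi_count, 5L)
  ## 2-primer input passes through unchanged
  twoP <- toyCounts("A", "C")
  expect_identical(collapseFourPrimer(twoP), twoP)
})

test_that("depth normalisation is counts-per-scale and replicate averaging restores mean depth", {
  counts <- toyCounts(bc1 = c("A", "B"), bc2 = c("C", "D"),
                      reads = c(10L, 990L), umis = c(5L, 495L))
  norm <- normalizeCounts(counts)
  expect_equal(norm$normalized_read_count[1], 10 / 1000 * 1e6)
  two <- rbind(counts, transform(counts, replicate_id = "rep2"))
  avg <- averageParentalCounts(two)
  expect_equal(avg$reads[avg$bc1 == "A"], 10)
  expect_equal(avg$umis[avg$bc1 == "A"], 5)
})

test_that("well barcode sets use the population-sd cutoff", {
  counts <- toyCounts(bc1 = letters[1:5], bc2 = LETTERS[1:5],
                      reads = c(10L, 10L, 10L, 100L, 100L))
  out <- deriveWellBarcodeSet(counts, minWellReads = 100)
  ## mean 46, population sd sqrt(1944) = 44.09: only the 100s exceed 90.09
  expect_identical(sort(out$bc1), c("d", "e"))
  ## all-equal counts yield an empty set
  eq <- toyCounts(letters[1:3], LETTERS[1:3], reads = 50L)
  expect_equal(nrow(deriveWellBarcodeSet(eq, minWellReads = 100)), 0L)
  ## single pair: sd 0, value not above mean
  single <- toyCounts("a", "A", reads = 200L)
  expect_equal(nrow(deriveWellBarcodeSet(single, minWellReads = 100)), 0L)
  ## shallow wells are rejected
  shallow <- deriveWellBarcodeSet(counts, minWellReads = 1e5)
  expect_true(attr(shallow, "wellRejected"))
})

test_that("rearrangement calling requires bonafide barcodes, novelty and UMI support", {
  bona <- toyInsertions(orientation = c("top-CS2", "top-CS2"))
  ## novel recombination of bc1 of insertion 1 with bc2 of insertion 2
  obsNovel <- toyCounts(bona$bc1[1], bona$bc2[2], umis = 3L)
  calls <- callRearrangements(obsNovel, bona)
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$class, "deletion")
  ## parental pair is not novel
  expect_equal(nrow(callRearrangements(toyCounts(bona$bc1[1], bona$bc2[1]),
                                       bona)), 0L)
  ## unknown barcode is not called
  expect_equal(nrow(callRearrangements(
    toyCounts(bona$bc1[1], strrep("N", 20)), bona)), 0L)
  ## single-UMI support is not called
  expect_equal(nrow(callRearrangements(
    toyCounts(bona$bc1[1], bona$bc2[2], umis = 1L), bona)), 0L)
})

test_that("classification follows chromosome and orientation geometry", {
  del <- toyInsertions(orientation = c("top-CS2", "top-CS2"),
                       pos = c(1000000L, 3500000L))
  calls <- classifySv(toyCounts(del$bc1[1], del$bc2[2]),
                      del[1, ], del[2, ])
  expect_identical(calls$class, "deletion")
  expect_equal(calls$size, 2500000L)
  inv <- toyInsertions(orientation = c("top-CS2", "bottom-CS1"))
  expect_identical(classifySv(toyCounts(inv$bc1[1], inv$bc2[2]),
                              inv[1, ], inv[2, ])$class, "inversion")
  tra <- toyInsertions(chrom = c("chr1", "chr2"))
  cc <- classifySv(toyCounts(tra$bc1[1], tra$bc2[2]), tra[1, ], tra[2, ])
  expect_identical(cc$class, "translocation")
  expect_true(is.na(cc$size))
})

test_that("deletion topology matches the barcode bookkeeping for both orientations", {
  ins <- toyInsertions(orientation = c("top-CS2", "top-CS2"),
                       pos = c(1000L, 1100L))
  ## X left, Y right, top-CS2: (bc1_X, bc2_Y) is the scar,
  ## (bc1_Y, bc2_X) the circle
  expect_identical(classifyDeletionTopology(ins[1, ], ins[2, ]),
                   "genomic_scar")
  expect_identical(classifyDeletionTopology(ins[2, ], ins[1, ]), "ecDNA")
  bot <- toyInsertions(orientation = c("bottom-CS1", "bottom-CS1"),
                       pos = c(1000L, 1100L))
  ## mirrored for bottom-CS1 pairs
  expect_identical(classifyDeletionTopology(bot[1, ], bot[2, ]), "ecDNA")
  expect_identical(classifyDeletionTopology(bot[2, ], bot[1, ]),
                   "genomic_scar")
})

test_that("replicate intersection flags pairs seen in both replicates", {
  bona <- toyInsertions(orientation = c("top-CS2", "top-CS2"))
  r1 <- callRearrangements(toyCounts(bona$bc1[1], bona$bc2[2], umis = 3L),
                           bona)
  r2empty <- callRearrangements(toyCounts(bona$bc1[1], bona$bc2[1]), bona)
  out <- intersectReplicates(r1, r1)
  expect_true(all(out$replicated))
  out2 <- intersectReplicates(r1, r2empty)
  expect_false(any(out2$replicated))
})

test_that("IVT validation supports pairs found post-Cre but not in parental data", {
  bona <- toyInsertions(orientation = c("top-CS2", "top-CS2"))
  calls <- callRearrangements(toyCounts(bona$bc1[1], bona$bc2[2],
                                        umis = 3L), bona)
  postClusters <- data.frame(chrom = "chr1", position = 999L,
                             barcode1 = bona$bc1[1],
                             barcode2 = bona$bc2[2],
                             cassette_strand = "top-CS2",
                             stringsAsFactors = FALSE)
  v <- validateWithIvt(calls, postClusters)
  expect_true(all(v$ivt_supported))
  ## same pair in the parental IVT clusters disqualifies it
  v2 <- validateWithIvt(calls, postClusters, postClusters)
  expect_false(any(v2$ivt_supported))
  ## absent from post-Cre data: unsupported
  v3 <- validateWithIvt(calls, postClusters[0, ])
  expect_false(any(v3$ivt_supported))
  ## bottom-strand clusters are canonicalised before comparison
  postBottom <- data.frame(chrom = "chr1", position = 1003L,
                           barcode1 = revComp(bona$bc2[2]),
                           barcode2 = revComp(bona$bc1[1]),
                           cassette_strand = "bottom-CS1",
                           stringsAsFactors = FALSE)
  expect_true(all(validateWithIvt(calls, postBottom)$ivt_supported))
})
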