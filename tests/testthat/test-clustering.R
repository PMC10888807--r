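makeObs <- function(bc1, bc2, chrom = "chr1", position = 1000L,
                    strand = "-", cassette = "top-CS2",
                    allele = "noVariant", len = 50L) {
  n <- length(bc1)
  len <- rep_len(len, n)
  ## minus-strand alignments pin their 0-based start at `position`,
  ## plus-strand alignments their 1-based inclusive end
  data.frame(read_id = sprintf("r%03d", seq_len(n)), barcode1 = bc1,
             barcode2 = bc2, cassette_strand = cassette, chrom = chrom,
             align_start = if (strand == "-") position + 1L else
               position - len + 1L,
             align_end = if (strand == "-") position + len else position,
             genome_strand = strand,
             umi1 = sprintf("U%03d", seq_len(n)),
             umi2 = sprintf("V%03d", seq_len(n)),
             multimapped = FALSE, junction_is_ttaa = TRUE,
             allele_call = rep_len(allele, n), stringsAsFactors = FALSE)
}

test_that("observations within the joint Levenshtein budget merge; beyond it they split", {
  set.seed(42)
  base1 <- strrep("ACGT", 5)
  base2 <- strrep("GTCA", 5)
  ## 3 substitutions across the two barcodes: joint distance 3 <= 6
  near <- makeObs(c(base1, mutateString(base1, 2)),
                  c(base2, mutateString(base2, 1)))
  cl <- clusterObservations(near)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$read_count, 2L)
  ## joint distance 7 > 6 splits
  far <- makeObs(c(base1, mutateString(base1, 4)),
                 c(base2, mutateString(base2, 3)))
  expect_equal(nrow(clusterObservations(far)), 2L)
})

test_that("cluster allele is the majority ignoring noVariant members", {
  obs <- makeObs(rep(strrep("A", 20), 7), rep(strrep("C", 20), 7),
                 allele = c("BL6", "BL6", rep("noVariant", 5)))
  cl <- clusterObservations(obs)
  expect_identical(cl$allele, "BL6")
  ## all-noVariant clusters stay noVariant
  obs2 <- makeObs(rep(strrep("A", 20), 3), rep(strrep("C", 20), 3))
  expect_identical(clusterObservations(obs2)$allele, "noVariant")
})

test_that("single-linkage clustering equals brute-force connected components on random instances", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(3:25, 1)
    nSeeds <- sample(1:3, 1)
    seeds1 <- replicate(nSeeds, randomBc(20))
    seeds2 <- replicate(nSeeds, randomBc(20))
    pick <- sample(nSeeds, n, replace = TRUE)
    bc1 <- vapply(pick, function(i) mutateString(seeds1[i], sample(0:4, 1)),
                  character(1))
    bc2 <- vapply(pick, function(i) mutateString(seeds2[i], sample(0:4, 1)),
                  character(1))
    d <- jointLevenshtein(bc1, bc2)
    mine <- shuffleseq:::componentsUnderThreshold(d, 6L)
    oracle <- bruteComponents(d, 6L)
    ## same partition up to label names
    expect_equal(length(unique(mine)), length(unique(oracle)))
    expect_true(all(tapply(oracle, mine, function(x)
      length(unique(x)) == 1L)))
    expect_true(all(tapply(mine, oracle, function(x)
      length(unique(x)) == 1L)))
  }
})

test_that("cluster pairing accepts only the exact 4-bp offset with opposite strands and revcomp barcodes", {
  bc1 <- "ACGTACGTACGTACGTACGT"; bc2 <- "GGTTCCAAGGTTCCAAGGTT"
  minus <- makeObs(revComp(bc2), revComp(bc1), position = 1000L,
                   strand = "-", cassette = "bottom-CS1")
  plus <- makeObs(bc1, bc2, position = 1004L, strand = "+",
                  cassette = "top-CS2")
  ## minus-strand cluster at p, plus at p+4: valid pair at 1-based 1001
  cl <- clusterObservations(rbind(minus, plus))
  pr <- pairClusters(cl)
  expect_equal(nrow(pr$candidates), 1L)
  expect_equal(pr$candidates$pos, 1001L)
  expect_identical(pr$candidates$orientation, "bottom-CS1")
  expect_identical(pr$candidates$bc1, bc1)
  expect_identical(pr$candidates$bc2, bc2)
  ## offset 5 does not pair
  plus5 <- makeObs(bc1, bc2, position = 1005L, strand = "+",
                   cassette = "top-CS2")
  pr5 <- pairClusters(clusterObservations(rbind(minus, plus5)))
  expect_equal(nrow(pr5$candidates), 0L)
  expect_equal(nrow(pr5$unpaired), 2L)
  ## same cassette strand does not pair
  plusSame <- makeObs(revComp(bc2), revComp(bc1), position = 1004L,
                      strand = "+", cassette = "bottom-CS1")
  expect_equal(nrow(pairClusters(clusterObservations(
    rbind(minus, plusSame)))$candidates), 0L)
})

test_that("replicate merging keeps shared clusters and reconciles alleles", {
  a <- makeObs(rep(strrep("A", 20), 6), rep(strrep("C", 20), 6),
               allele = "BL6")
  b <- makeObs(rep(strrep("G", 20), 6), rep(strrep("T", 20), 6),
               position = 2000L, allele = "CAST")
  rep1 <- clusterObservations(rbind(a, b))
  rep2 <- clusterObservations(a)
  merged <- mergeReplicates(list(rep1, rep2))
  expect_equal(nrow(merged), 1L)   # cluster b present in one replicate only
  expect_identical(merged$allele, "BL6")
  ## identical inputs merge to identity with per-replicate counts
  m2 <- mergeReplicates(list(rep1, rep1))
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$read_count_rep1, m2$read_count_rep2)
  ## incongruent replicate alleles become inconclusive
  expect_identical(assignInsertionAllele("BL6", "CAST"), "inconclusive")
  expect_identical(assignInsertionAllele("BL6", "noVariant"), "BL6")
  expect_identical(assignInsertionAllele("noVariant", "noVariant"),
                   "noVariant")
})
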