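t7rec <- function(cell, umi, bc1, bc2, side = "CS2", n = 1L) {
  data.frame(cell_bc = cell, umi = umi, bc1 = bc1, bc2 = bc2,
             capture_side = side, stringsAsFactors = FALSE)[
               rep(1L, n), , drop = FALSE]
}

test_that("T7 read formatting and extraction round-trip both capture layouts", {
  reads <- data.frame(cell_bc = strrep("A", 16), umi = strrep("T", 12),
                      bc1 = "ACGTACGTACGTACGTACGT",
                      bc2 = "GGTTCCAAGGTTCCAAGGTT",
                      capture_side = c("CS2", "CS1"),
                      stringsAsFactors = FALSE)
  fmt <- formatT7Reads(reads)
  rec <- extractT7Records(fmt)
  expect_equal(nrow(rec), 2L)
  expect_identical(rec$capture_side, c("CS2", "CS1"))
  ## CS1 capture extracts BC2 first; both re-orient to canonical barcodes
  expect_identical(unique(rec$bc1), reads$bc1[1])
  expect_identical(unique(rec$bc2), reads$bc2[1])
  ## anchors outside the expected window are rejected
  shifted <- fmt
  shifted$read2 <- paste0(strrep("A", 30), shifted$read2)
  expect_equal(nrow(extractT7Records(shifted)), 0L)
  ## whitelist filtering is exact
  expect_equal(nrow(extractT7Records(fmt, whitelist = strrep("G", 16))),
               0L)
})

test_that("chimeric UMIs are dropped below a 20% read share", {
  ## reads split 9:1 between two pairs under one UMI
  recs <- rbind(t7rec("c1", "U1", "A", "B", n = 9L),
                t7rec("c1", "U1", "C", "D", n = 1L))
  out <- filterChimericUmis(recs)
  expect_equal(nrow(out), 1L)
  expect_identical(out$bc1, "A")
  ## a 50:50 split keeps both
  even <- rbind(t7rec("c1", "U1", "A", "B", n = 2L),
                t7rec("c1", "U1", "C", "D", n = 2L))
  expect_equal(nrow(filterChimericUmis(even)), 2L)
  ## a single pair under a UMI is kept (share 1)
  expect_equal(nrow(filterChimericUmis(t7rec("c1", "U1", "A", "B"))), 1L)
})

test_that("UMI collapse counts Hamming-1 connected components", {
  u <- function(x) paste0(x, strrep("A", 12L - nchar(x)))
  ## distance-1 pair collapses to one component
  recs <- rbind(t7rec("c1", u("AAAA"), "A", "B"),
                t7rec("c1", u("AAAT"), "A", "B"))
  expect_equal(collapseUmis(recs)$umi_count, 1L)
  ## all-distinct UMIs at distance >= 2 stay separate
  far <- do.call(rbind, lapply(c("AACC", "GGTT", "CCGG", "TTAA", "ACGT"),
                               function(x) t7rec("c1", u(x), "A", "B")))
  expect_equal(collapseUmis(far)$umi_count, 5L)
  ## a chain u1-u2-u3 of consecutive distance 1 is one component
  chain <- do.call(rbind, lapply(c("AAAA", "AAAT", "AATT"),
                                 function(x) t7rec("c1", u(x), "A", "B")))
  expect_equal(collapseUmis(chain)$umi_count, 1L)
})

test_that("UMI collapse equals brute-force components on random instances", {
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(2:30, 1)
    base <- randomBc(12)
    umis <- vapply(seq_len(n), function(i)
      mutateString(base, sample(0:3, 1)), character(1))
    recs <- do.call(rbind, lapply(umis, function(x) t7rec("c1", x, "A", "B")))
    d <- shuffleseq:::hammingDistance(unique(umis))
    expect_equal(collapseUmis(recs)$umi_count,
                 length(unique(bruteComponents(d, 1L))))
  }
})

test_that("matrix building sums capture sides and keeps marginals consistent", {
  counts <- data.frame(cell_bc = c("c1", "c1", "c2"),
                       bc1 = "A", bc2 = "B",
                       capture_side = c("CS2", "CS1", "CS2"),
                       umi_count = c(3L, 2L, 4L), stringsAsFactors = FALSE)
  mat <- buildBcCellMatrix(counts)
  expect_equal(dim(mat), c(1L, 2L))
  expect_equal(as.numeric(mat["A|B", "c1"]), 5)
  expect_equal(sum(mat), sum(counts$umi_count))
  expect_equal(nrow(buildBcCellMatrix(counts[0, ])), 0L)
})

test_that("cell QC applies the transcriptome thresholds", {
  qc <- data.frame(cell_bc = c("a", "b", "c", "d"),
                   transcriptome_umis = c(1500, 900, 1500, 1500),
                   mito_fraction = c(5, 5, 13, 5),
                   doublet_score = c(0.1, 0.1, 0.1, 0.45))
  expect_identical(qcCells(qc), "a")
})

test_that("hamming distance requires equal lengths", {
  expect_error(hammingDistance(c("AAA", "AAAA")), "equal-length")
})
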